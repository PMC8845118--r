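# MS1 annotation: adduct mass arithmetic, ppm-tolerance library matching,
# and bounded molecular-formula enumeration with an RDBE/parity filter.
# All mass arithmetic uses one embedded monoisotopic table so results are
# bit-reproducible with no external mass database.

# Monoisotopic masses (Da) of the supported elements.
ELEMENT_MASSES <- c(C = 12.0, H = 1.007825032, N = 14.003074005,
                    O = 15.994914620, S = 31.972071174)

# Mass of a proton; the electron mass is absorbed into the proton-transfer
# convention used for +/-H quasimolecular ions.
PROTON_MASS <- 1.007276466

#' Default adduct rule table
#'
#' Singly charged proton-transfer quasimolecular ions: `[M+H]+` in positive
#' mode and `[M-H]-` in negative mode. The table can be extended by the
#' caller with additional rows (`name`, `mass_shift`, `polarity`, `charge`).
#'
#' @return A data.frame of adduct rules.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M-H]-"),
    mass_shift = c(PROTON_MASS, -PROTON_MASS),
    polarity = c("positive", "negative"),
    charge = c(1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of an adduct of a neutral molecule
#'
#' For singly charged ions this is `neutral_mass + mass_shift`; for higher
#' charge states the shifted mass is divided by `|charge|`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct One row of an adduct rule table.
#' @return Theoretical m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be positive", call. = FALSE)
  z <- abs(adduct$charge)
  if (z == 0L) stop("adduct charge must be non-zero", call. = FALSE)
  mz <- (neutral_mass + adduct$mass_shift) / z
  if (any(mz <= 0)) stop("invalid adduct: non-positive m/z", call. = FALSE)
  mz
}

#' Relative mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da, > 0).
#' @return `|observed - theoretical| / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive", call. = FALSE)
  abs(observed - theoretical) / theoretical * 1e6
}

#' Match MS1 peaks against a compound library
#'
#' For each peak, every (compound, adduct) combination whose adduct polarity
#' matches the peak's ion mode and whose mass error is within `tol_ppm`
#' (inclusive) is reported. Matching is mass-only: the library carries no
#' retention times, and the output is flagged accordingly via the
#' `rt_checked` attribute.
#'
#' @param peaks data.frame with `peak_id`, `mz`, `ion_mode` (and optionally
#'   `rt_min`, `intensity`).
#' @param library A `compound_library`.
#' @param adducts Adduct rule table, default [default_adducts()].
#' @param tol_ppm Inclusive mass tolerance in ppm, default 5.0.
#' @return data.frame of matches (`peak_id`, `compound_id`, `adduct`,
#'   `theoretical_mz`, `ppm_error`), sorted by peak then ascending ppm error.
#' @export
match_peaks <- function(peaks, library, adducts = default_adducts(), tol_ppm = 5.0) {
  stopifnot(inherits(library, "compound_library"), tol_ppm >= 0)
  empty <- data.frame(peak_id = character(), compound_id = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(library$compounds) == 0L) {
    attr(empty, "rt_checked") <- FALSE
    return(empty)
  }
  if (!all(peaks$ion_mode %in% c("positive", "negative"))) {
    stop("unknown ion_mode label in peak list", call. = FALSE)
  }
  # theoretical m/z table: one row per (compound, adduct)
  theo <- do.call(rbind, lapply(seq_len(nrow(adducts)), function(ai) {
    data.frame(
      compound_id = library$compounds$compound_id,
      adduct = adducts$name[ai],
      polarity = adducts$polarity[ai],
      theoretical_mz = adduct_mz(library$compounds$neutral_mass, adducts[ai, ]),
      stringsAsFactors = FALSE
    )
  }))
  out <- lapply(seq_len(nrow(peaks)), function(pi) {
    cand <- theo[theo$polarity == peaks$ion_mode[pi], , drop = FALSE]
    err <- ppm_error(peaks$mz[pi], cand$theoretical_mz)
    keep <- which(err <= tol_ppm)
    if (length(keep) == 0L) return(NULL)
    ord <- keep[order(err[keep], cand$compound_id[keep])]
    data.frame(peak_id = peaks$peak_id[pi],
               compound_id = cand$compound_id[ord],
               adduct = cand$adduct[ord],
               theoretical_mz = cand$theoretical_mz[ord],
               ppm_error = err[ord],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(list(empty), out))
  rownames(res) <- NULL
  attr(res, "rt_checked") <- FALSE
  res
}

#' Element bounds for formula enumeration
#'
#' @param C,H,N,O,S Length-2 integer vectors `c(min, max)` per element.
#' @return A named list of bounds, validated.
#' @export
element_bounds <- function(C = c(0L, 60L), H = c(0L, 100L), N = c(0L, 10L),
                           O = c(0L, 30L), S = c(0L, 4L)) {
  b <- list(C = as.integer(C), H = as.integer(H), N = as.integer(N),
            O = as.integer(O), S = as.integer(S))
  for (el in names(b)) {
    r <- b[[el]]
    if (length(r) != 2L || anyNA(r) || r[1L] < 0L || r[1L] > r[2L]) {
      stop("invalid bounds for element ", el, call. = FALSE)
    }
  }
  b
}

#' Ring-and-double-bond equivalents of a CHNOS formula
#'
#' `rdbe = C - H/2 + N/2 + 1`; oxygen and sulfur contribute zero.
#'
#' @param C,H,N Element counts (O and S are irrelevant).
#' @return RDBE value (may be negative or half-integer for invalid
#'   formulas; see [enumerate_formulas()] for the filter).
#' @export
rdbe <- function(C, H, N = 0) {
  C - H / 2 + N / 2 + 1
}

# Hill-notation formula string: C, then H, then remaining elements
# alphabetically; zero counts dropped, count 1 left implicit.
formula_string <- function(counts) {
  order_els <- c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  parts <- vapply(order_els, function(el) {
    n <- counts[[el]]
    if (is.na(n) || n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' Enumerate candidate molecular formulas for an observed ion
#'
#' Exhaustively searches the bounded CHNOS grid for neutral formulas whose
#' adduct m/z falls within `tol_ppm` (inclusive) of the observed m/z, then
#' filters on chemistry: RDBE must be a non-negative integer (the nitrogen
#' parity rule for even-electron neutral molecules; half-integer RDBE
#' candidates are rejected).
#'
#' @param mz Observed m/z (Da).
#' @param adduct One row of an adduct rule table (used to neutralize `mz`).
#' @param tol_ppm Inclusive tolerance in ppm.
#' @param bounds An [element_bounds()] list.
#' @return data.frame of candidates (`formula`, `C`, `H`, `N`, `O`, `S`,
#'   `theoretical_mass`, `rdbe`, `ppm_error`), sorted by ascending ppm
#'   error, ties by formula string.
#' @export
enumerate_formulas <- function(mz, adduct, tol_ppm = 5.0, bounds = element_bounds()) {
  stopifnot(tol_ppm >= 0)
  z <- abs(adduct$charge)
  target <- mz * z - adduct$mass_shift  # neutral monoisotopic mass
  if (target <= 0) stop("adduct neutralization gives non-positive mass", call. = FALSE)
  tol_da <- target * tol_ppm / 1e6
  grid <- expand.grid(C = seq(bounds$C[1L], bounds$C[2L]),
                      N = seq(bounds$N[1L], bounds$N[2L]),
                      O = seq(bounds$O[1L], bounds$O[2L]),
                      S = seq(bounds$S[1L], bounds$S[2L]))
  base_mass <- grid$C * ELEMENT_MASSES[["C"]] + grid$N * ELEMENT_MASSES[["N"]] +
    grid$O * ELEMENT_MASSES[["O"]] + grid$S * ELEMENT_MASSES[["S"]]
  remaining <- target - base_mass
  # window widened by a small absolute margin; the exact ppm filter below
  # (denominator = theoretical mass) decides inclusion
  margin <- tol_da + 1e-6
  h_lo <- pmax(bounds$H[1L], ceiling((remaining - margin) / ELEMENT_MASSES[["H"]]))
  h_hi <- pmin(bounds$H[2L], floor((remaining + margin) / ELEMENT_MASSES[["H"]]))
  rows <- which(h_lo <= h_hi)
  out <- lapply(rows, function(i) {
    H <- seq(h_lo[i], h_hi[i])
    mass <- base_mass[i] + H * ELEMENT_MASSES[["H"]]
    err <- ppm_error(target, mass)  # observed (neutralized) vs theoretical
    r <- rdbe(grid$C[i], H, grid$N[i])
    keep <- err <= tol_ppm & r >= 0 & abs(r - round(r)) < 1e-9
    if (!any(keep)) return(NULL)
    data.frame(C = grid$C[i], H = H[keep], N = grid$N[i], O = grid$O[i],
               S = grid$S[i], theoretical_mass = mass[keep], rdbe = r[keep],
               ppm_error = err[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), S = integer(),
                      theoretical_mass = numeric(), rdbe = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
    return(res)
  }
  res$formula <- vapply(seq_len(nrow(res)), function(i) {
    formula_string(list(C = res$C[i], H = res$H[i], N = res$N[i],
                        O = res$O[i], S = res$S[i]))
  }, character(1))
  res <- res[order(res$ppm_error, res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("formula", "C", "H", "N", "O", "S", "theoretical_mass", "rdbe", "ppm_error")]
}
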