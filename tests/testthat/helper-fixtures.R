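# Shared fixture builders. Bit positions are 0-based in set notation, so
# fp_bits(c(0, 1, 2), 8) sets the first three of eight bits.

fp_bits <- function(on, length = 8L) {
  v <- integer(length)
  v[on + 1L] <- 1L
  v
}

# Independent naive Tanimoto: explicit bit-by-bit counting.
naive_tanimoto <- function(a, b) {
  inter <- 0L; ca <- 0L; cb <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1L) ca <- ca + 1L
    if (b[i] == 1L) cb <- cb + 1L
    if (a[i] == 1L && b[i] == 1L) inter <- inter + 1L
  }
  if (ca + cb - inter == 0L) return(0)
  inter / (ca + cb - inter)
}

# Minimal compound library from explicit masses and fingerprints.
make_library <- function(masses, fps = NULL, ids = NULL, herbs = "BB") {
  n <- length(masses)
  if (is.null(ids)) ids <- sprintf("c%d", seq_len(n))
  if (is.null(fps)) fps <- matrix(1L, nrow = n, ncol = 8L)
  rownames(fps) <- ids
  structure(list(
    compounds = data.frame(compound_id = ids, name = ids,
                           herb = rep_len(herbs, n), neutral_mass = masses,
                           stringsAsFactors = FALSE),
    fingerprints = fps
  ), class = "compound_library")
}

# Minimal reference panel from a fingerprint matrix and target labels.
make_panel <- function(fps, targets) {
  ids <- sprintf("l%d", seq_len(nrow(fps)))
  rownames(fps) <- ids
  structure(list(
    ligands = data.frame(ligand_id = ids, target_id = targets,
                         stringsAsFactors = FALSE),
    fingerprints = fps
  ), class = "reference_panel")
}

# Monoisotopic neutral mass of glucose (C6H12O6) from the embedded table:
# 6*12 + 12*1.007825032 + 6*15.994914620
GLUCOSE_MASS <- 180.063388104

# Exhaustive hypergeometric upper tail by enumerating every n-subset of a
# universe of size N with K annotated elements.
enum_hypergeom_tail <- function(k, K, n, N) {
  draws <- utils::combn(seq_len(N), n)
  hits <- apply(draws, 2, function(d) sum(d <= K))
  mean(hits >= k)
}

# term_db from a named list of gene sets.
make_term_db <- function(terms, universe) {
  df <- data.frame(term_id = names(terms), term_name = names(terms),
                   group = "g1", stringsAsFactors = FALSE)
  df$genes <- unname(terms)
  structure(list(terms = df, universe = universe), class = "term_db")
}

# Independent brute-force formula enumeration over the full CHNOS grid.
brute_force_formulas <- function(mz, shift, tol_ppm, bounds) {
  target <- mz - shift
  grid <- expand.grid(C = bounds$C[1]:bounds$C[2], H = bounds$H[1]:bounds$H[2],
                      N = bounds$N[1]:bounds$N[2], O = bounds$O[1]:bounds$O[2],
                      S = bounds$S[1]:bounds$S[2])
  masses <- c(C = 12.0, H = 1.007825032, N = 14.003074005,
              O = 15.994914620, S = 31.972071174)
  m <- with(grid, C * masses["C"] + H * masses["H"] + N * masses["N"] +
              O * masses["O"] + S * masses["S"])
  err <- abs(target - m) / m * 1e6
  r <- with(grid, C - H / 2 + N / 2 + 1)
  keep <- is.finite(err) & err <= tol_ppm & r >= 0 & abs(r - round(r)) < 1e-9
  out <- grid[keep, , drop = FALSE]
  out[order(out$C, out$H, out$N, out$O, out$S), , drop = FALSE]
}
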