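# Study-scale constructors: the published degree table of the 19 core serum
# constituents of the Xijiao Dihuang Tang (XDT) decoction, a deterministic
# prediction table realizing the published network arithmetic (60 compounds,
# 338 targets, 985 distinct compound-target pairs), and the eight published
# pathology-category counts.

#' Published per-category target counts of the XDT serum-constituent study
#'
#' The eight pathology categories and the number of predicted targets
#' independently associated with each; the counts sum to 338.
#'
#' @format Named integer vector of length 8.
#' @export
xdt_pathology_counts <- c(
  "cell apoptosis" = 111L,
  "inflammation" = 79L,
  "oxidative stress" = 46L,
  "cell proliferation and differentiation" = 41L,
  "energy metabolism" = 27L,
  "neurotransmitter" = 18L,
  "coagulation" = 9L,
  "immunity" = 7L
)

#' Published degree table of the 19 core XDT serum constituents
#'
#' Reads the reported constituent-target degree table (degree >= 17)
#' shipped with the package: compound id, PubChem CID, molecule name and
#' network degree, topped by adenosine with degree 75.
#'
#' @return data.frame (`rank`, `compound_id`, `pubchem_cid`, `name`,
#'   `degree`).
#' @export
xdt_core_degrees <- function() {
  path <- system.file("extdata", "core_constituent_degrees.tsv",
                      package = "serumnetpharm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Deterministic filler degrees: 41 compounds below the core threshold whose
# degrees sum to 985 - 667 = 318 (31 compounds of degree 8, 10 of degree 7),
# completing the 60-compound / 985-edge arithmetic.
filler_degrees <- function() {
  rep(c(8L, 7L), times = c(31L, 10L))
}

#' Study-scale prediction table realizing the published network arithmetic
#'
#' Constructs a deterministic compound-target prediction table with exactly
#' 60 compounds, 338 targets and 985 distinct pairs, in which the 19 core
#' constituents carry their published degrees and 41 filler constituents
#' carry sub-threshold degrees. Targets are assigned by a least-loaded
#' greedy rule so every target is connected and every pair is distinct.
#'
#' @param seed Integer seed; only the filler ordering and the cosmetic
#'   similarity scores depend on it, the degree structure is fixed.
#' @return Prediction data.frame (`compound_id`, `target_id`, `score`,
#'   `source`).
#' @export
paper_scale_predictions <- function(seed = 1L) {
  core <- xdt_core_degrees()
  with_seed(stage_seed(seed, "predictions"), {
    fill_deg <- sample(filler_degrees())
    compounds <- data.frame(
      compound_id = c(core$compound_id, sprintf("FL%02d", seq_along(fill_deg))),
      degree = c(core$degree, fill_deg),
      stringsAsFactors = FALSE
    )
    targets <- sprintf("TGT%03d", seq_len(338L))
    load <- integer(length(targets))
    edges <- vector("list", nrow(compounds))
    ord <- order(-compounds$degree)
    for (i in ord) {
      d <- compounds$degree[i]
      pick <- order(load, seq_along(targets))[seq_len(d)]
      load[pick] <- load[pick] + 1L
      edges[[i]] <- data.frame(compound_id = compounds$compound_id[i],
                               target_id = targets[pick],
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, edges)
    res$score <- round(stats::runif(nrow(res), 0.4, 1), 3L)
    res$source <- "similarity"
    rownames(res) <- NULL
    res
  })
}

#' Study-scale target-category map realizing the published counts
#'
#' Assigns the 338 targets of [paper_scale_predictions()] to the eight
#' pathology categories with the published per-category counts
#' (111, 79, 46, 41, 27, 18, 9, 7), one category per target.
#'
#' @param targets Character vector of exactly 338 target ids, default the
#'   targets of the study-scale network.
#' @param seed Integer seed shuffling which target lands in which category.
#' @return data.frame (`target_id`, `category`).
#' @export
paper_scale_category_map <- function(targets = sprintf("TGT%03d", seq_len(338L)),
                                     seed = 1L) {
  counts <- xdt_pathology_counts
  if (length(targets) != sum(counts)) {
    stop("expected exactly ", sum(counts), " targets", call. = FALSE)
  }
  with_seed(stage_seed(seed, "categories"), {
    shuffled <- sample(targets)
    data.frame(target_id = shuffled,
               category = rep(names(counts), times = counts),
               stringsAsFactors = FALSE)
  })
}

#' Assign synthetic targets to pathology categories
#'
#' Maps an arbitrary target set to the eight study pathology labels (or a
#' custom label set), one category per target, with seeded multinomial
#' assignment. Used by the pipeline when the prediction table is synthetic.
#'
#' @param targets Character vector of target ids.
#' @param seed Integer seed.
#' @param labels Category labels, default the eight study pathologies.
#' @return data.frame (`target_id`, `category`).
#' @export
gen_category_map <- function(targets, seed = 1L,
                             labels = names(xdt_pathology_counts)) {
  if (length(targets) == 0L) {
    return(data.frame(target_id = character(), category = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(stage_seed(seed, "categories"), {
    data.frame(target_id = targets,
               category = sample(labels, length(targets), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
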