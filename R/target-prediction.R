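# Ligand-based target prediction: per-target maximum Tanimoto score over a
# reference ligand panel, inclusive similarity threshold (default 0.4), and
# a union merge with table-sourced database predictions.

#' Predict targets for one compound by fingerprint similarity
#'
#' Scores the compound against every reference ligand, aggregates per target
#' by the maximum Tanimoto score (the similarity-ensemble convention), and
#' keeps targets whose score reaches the threshold (inclusive).
#'
#' @param fingerprint 0/1 bit vector for the query compound.
#' @param panel A `reference_panel` (see [gen_reference_panel()]) or a list
#'   with `ligands` (data.frame `ligand_id`, `target_id`) and `fingerprints`
#'   matrix.
#' @param threshold Inclusive similarity cutoff in `[0, 1]`, default 0.4.
#' @param compound_id Id recorded in the output, default `"query"`.
#' @return data.frame (`compound_id`, `target_id`, `score`, `source`)
#'   sorted by descending score, ties by target id.
#' @export
predict_targets_by_similarity <- function(fingerprint, panel, threshold = 0.4,
                                          compound_id = "query") {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(fingerprint) == 0L) stop("empty fingerprint", call. = FALSE)
  if (nrow(panel$ligands) == 0L) return(empty_predictions())
  if (ncol(panel$fingerprints) != length(fingerprint)) {
    stop("fingerprint length does not match panel", call. = FALSE)
  }
  s <- tanimoto_matrix(matrix(fingerprint, nrow = 1L), panel$fingerprints)[1L, ]
  per_target <- tapply(s, panel$ligands$target_id, max)
  keep <- per_target >= threshold
  res <- data.frame(
    compound_id = rep(compound_id, sum(keep)),
    target_id = names(per_target)[keep],
    score = as.numeric(per_target[keep]),
    source = rep("similarity", sum(keep)),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$score, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict targets for every compound in a library
#'
#' Applies [predict_targets_by_similarity()] across a whole
#' `compound_library` in one vectorized pass.
#'
#' @param library A `compound_library`.
#' @param panel A `reference_panel`.
#' @param threshold Inclusive similarity cutoff, default 0.4.
#' @return data.frame (`compound_id`, `target_id`, `score`, `source`)
#'   sorted by compound id, then descending score, then target id.
#' @export
predict_targets <- function(library, panel, threshold = 0.4) {
  stopifnot(inherits(library, "compound_library"))
  if (nrow(library$compounds) == 0L || nrow(panel$ligands) == 0L) {
    return(empty_predictions())
  }
  s <- tanimoto_matrix(library$fingerprints, panel$fingerprints)
  targets <- panel$ligands$target_id
  utarg <- sort(unique(targets))
  # per-target max over ligand columns, all compounds at once
  per_target <- vapply(utarg, function(t) {
    cols <- which(targets == t)
    if (length(cols) == 1L) s[, cols] else apply(s[, cols, drop = FALSE], 1L, max)
  }, numeric(nrow(s)))
  if (nrow(library$compounds) == 1L) per_target <- matrix(per_target, nrow = 1L)
  hits <- which(per_target >= threshold, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_predictions())
  res <- data.frame(
    compound_id = library$compounds$compound_id[hits[, 1L]],
    target_id = utarg[hits[, 2L]],
    score = per_target[hits],
    source = "similarity",
    stringsAsFactors = FALSE
  )
  res <- res[order(res$compound_id, -res$score, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge similarity and database target predictions
#'
#' Union of the two prediction tables keyed on (compound, target): one
#' record per pair, score equal to the maximum contributing score, and
#' source `"both"` when the pair occurs in both inputs.
#'
#' @param sim data.frame of similarity predictions.
#' @param db data.frame of database predictions (`compound_id`, `target_id`,
#'   optional `score` defaulting to 1.0).
#' @return Merged data.frame (`compound_id`, `target_id`, `score`,
#'   `source`), sorted by compound then descending score then target.
#' @export
merge_predictions <- function(sim, db) {
  sim <- normalize_predictions(sim, "similarity")
  db <- normalize_predictions(db, "database")
  all <- rbind(sim, db)
  if (nrow(all) == 0L) return(empty_predictions())
  key <- paste(all$compound_id, all$target_id, sep = "\r")
  agg <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    srcs <- unique(all$source[idx])
    data.frame(compound_id = all$compound_id[idx[1L]],
               target_id = all$target_id[idx[1L]],
               score = max(all$score[idx]),
               source = if (length(srcs) > 1L) "both" else srcs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$compound_id, -res$score, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

normalize_predictions <- function(x, default_source) {
  if (is.null(x) || nrow(x) == 0L) return(empty_predictions())
  if (is.null(x$score)) x$score <- 1.0
  if (is.null(x$source)) x$source <- default_source
  x[, c("compound_id", "target_id", "score", "source")]
}

empty_predictions <- function() {
  data.frame(compound_id = character(), target_id = character(),
             score = numeric(), source = character(), stringsAsFactors = FALSE)
}

#' Precision and recall of predictions against planted truth
#'
#' @param predictions data.frame with `compound_id`, `target_id`.
#' @param truth_pairs data.frame of true (compound_id, target_id) pairs.
#' @return Named numeric vector with `precision`, `recall`, `tp`, `fp`,
#'   `fn`. Precision of an empty prediction set is defined as 1.
#' @export
prediction_metrics <- function(predictions, truth_pairs) {
  pkey <- unique(paste(predictions$compound_id, predictions$target_id, sep = "\r"))
  tkey <- unique(paste(truth_pairs$compound_id, truth_pairs$target_id, sep = "\r"))
  tp <- length(intersect(pkey, tkey))
  fp <- length(setdiff(pkey, tkey))
  fn <- length(setdiff(tkey, pkey))
  c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0L) 1 else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn)
}
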