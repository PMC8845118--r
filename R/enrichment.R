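# Over-representation analysis: one-sided hypergeometric test per term,
# Benjamini-Hochberg (or Bonferroni) correction, and functional-group
# percentage shares of the significant terms.

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` study genes are drawn from
#' a universe of `N` genes of which `K` carry the annotation. Computed via
#' the log-space survival function of [stats::phyper()].
#'
#' @param k Observed overlap count.
#' @param K Term (annotation) size.
#' @param n Study-set size.
#' @param N Universe size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  # upper tail including k; exp of the log survival function keeps
  # precision for extreme tails
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric over-representation analysis of a study set
#'
#' Tests each term of the database for over-representation in the study set
#' with the one-sided hypergeometric test, then adjusts over all tested
#' terms. Terms with zero overlap are excluded from the family by default
#' (`test_all_terms = TRUE` includes them), matching common ORA-tool
#' behavior.
#'
#' @param study Character vector of gene ids, a non-empty subset of the
#'   database universe.
#' @param db A `term_db` (see [gen_term_db()] / [read_gmt()]).
#' @param alpha Significance level applied to adjusted p-values when
#'   flagging significance, default 0.05.
#' @param correction `"BH"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @param universe Optional explicit background; defaults to the database
#'   universe.
#' @param test_all_terms Include zero-overlap terms in the testing family.
#' @return data.frame (`term_id`, `term_name`, `group`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `significant`), sorted by ascending p, ties by
#'   term id.
#' @export
ora <- function(study, db, alpha = 0.05, correction = c("BH", "bonferroni"),
                universe = NULL, test_all_terms = FALSE) {
  correction <- match.arg(correction)
  stopifnot(inherits(db, "term_db"))
  if (length(study) == 0L) stop("study set is empty", call. = FALSE)
  if (is.null(universe)) universe <- db$universe
  study <- unique(study)
  missing <- setdiff(study, universe)
  if (length(missing) > 0L) {
    stop("study genes absent from the universe: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...", call. = FALSE)
  }
  N <- length(universe)
  n <- length(study)
  terms <- db$terms
  if (nrow(terms) == 0L) return(empty_enrichment())
  K <- vapply(terms$genes, function(g) length(intersect(g, universe)), integer(1))
  k <- vapply(terms$genes, function(g) length(intersect(g, study)), integer(1))
  keep <- if (test_all_terms) rep(TRUE, nrow(terms)) else k >= 1L
  if (!any(keep)) return(empty_enrichment())
  res <- data.frame(
    term_id = terms$term_id[keep],
    term_name = terms$term_name[keep],
    group = terms$group[keep],
    k = k[keep], K = K[keep], n = n, N = N,
    stringsAsFactors = FALSE
  )
  res$p <- hypergeom_pvalue(res$k, res$K, res$n, res$N)
  res$p_adj <- stats::p.adjust(res$p, method = if (correction == "BH") "BH" else "bonferroni")
  res$significant <- res$p_adj <= alpha
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "metadata") <- list(test = "hypergeometric (upper tail)",
                                correction = correction, alpha = alpha,
                                universe_size = N, study_size = n)
  res
}

empty_enrichment <- function() {
  data.frame(term_id = character(), term_name = character(), group = character(),
             k = integer(), K = integer(), n = integer(), N = integer(),
             p = numeric(), p_adj = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' Functional-group percentage shares of significant terms
#'
#' ClueGO-style report: the share of each functional group among the
#' significant terms, `100 * (significant terms in group) / (total
#' significant terms)`, displayed to two decimals.
#'
#' @param significant data.frame of enrichment results (typically the
#'   `significant == TRUE` rows of an [ora()] result) with a `group`
#'   column.
#' @return data.frame (`group`, `n_terms`, `share`) with shares summing to
#'   100 within rounding; empty when no terms are supplied.
#' @export
group_shares <- function(significant) {
  if (is.null(significant) || nrow(significant) == 0L) {
    return(data.frame(group = character(), n_terms = integer(),
                      share = numeric(), stringsAsFactors = FALSE))
  }
  counts <- table(significant$group)
  total <- sum(counts)
  res <- data.frame(group = names(counts), n_terms = as.integer(counts),
                    share = round(100 * as.integer(counts) / total, 2L),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_terms, res$group), , drop = FALSE]
  rownames(res) <- NULL
  res
}
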