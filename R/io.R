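# Plain-text readers and writers for every artifact the pipeline exchanges:
# compound library TSV (fingerprints hex-encoded), reference panel TSV,
# peak list CSV, prediction TSV, STRING-style PPI TSV, GMT term files, and
# planted-truth JSON.

#' Write a compound library to TSV
#'
#' Columns: `compound_id`, `name`, `herb`, `neutral_mass`,
#' `fingerprint_hex`. Masses are written at full precision.
#'
#' @param library A `compound_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(library, path) {
  df <- library$compounds
  df$neutral_mass <- sprintf("%.9f", df$neutral_mass)
  df$fingerprint_hex <- apply(library$fingerprints, 1L, fp_to_hex)
  df$fp_length <- ncol(library$fingerprints)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound library from TSV
#'
#' @param path Path to a TSV written by [write_compound_library()].
#' @return A `compound_library`.
#' @export
read_compound_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(neutral_mass = "character"))
  need <- c("compound_id", "name", "herb", "neutral_mass", "fingerprint_hex", "fp_length")
  if (!all(need %in% names(df))) {
    stop("compound library file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  fp_len <- unique(df$fp_length)
  if (length(fp_len) > 1L) stop("inconsistent fingerprint lengths", call. = FALSE)
  fps <- if (nrow(df) > 0L) {
    t(vapply(df$fingerprint_hex, fp_from_hex, integer(fp_len[1L]), length = fp_len[1L]))
  } else matrix(integer(), 0L, if (length(fp_len)) fp_len[1L] else 0L)
  rownames(fps) <- df$compound_id
  structure(list(
    compounds = data.frame(compound_id = df$compound_id, name = df$name,
                           herb = df$herb,
                           neutral_mass = as.numeric(df$neutral_mass),
                           stringsAsFactors = FALSE),
    fingerprints = fps
  ), class = "compound_library")
}

#' Write a reference ligand panel to TSV
#'
#' Columns: `ligand_id`, `target_id`, `fingerprint_hex`, `fp_length`.
#'
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  df <- panel$ligands
  df$fingerprint_hex <- apply(panel$fingerprints, 1L, fp_to_hex)
  df$fp_length <- ncol(panel$fingerprints)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference ligand panel from TSV
#'
#' @param path Path to a TSV written by [write_reference_panel()].
#' @return A `reference_panel`.
#' @export
read_reference_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "target_id", "fingerprint_hex", "fp_length")
  if (!all(need %in% names(df))) {
    stop("panel file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  fp_len <- unique(df$fp_length)
  if (length(fp_len) > 1L) stop("inconsistent fingerprint lengths", call. = FALSE)
  fps <- if (nrow(df) > 0L) {
    t(vapply(df$fingerprint_hex, fp_from_hex, integer(fp_len[1L]), length = fp_len[1L]))
  } else matrix(integer(), 0L, if (length(fp_len)) fp_len[1L] else 0L)
  rownames(fps) <- df$ligand_id
  structure(list(
    ligands = data.frame(ligand_id = df$ligand_id, target_id = df$target_id,
                         stringsAsFactors = FALSE),
    fingerprints = fps
  ), class = "reference_panel")
}

#' Write an MS1 peak list to CSV
#'
#' Columns: `peak_id`, `mz`, `rt_min`, `ion_mode`, `intensity`.
#'
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  out <- peaks
  out$mz <- sprintf("%.9f", out$mz)
  utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MS1 peak list from CSV
#'
#' @param path Path to a CSV with columns `peak_id`, `mz`, `rt_min`,
#'   `ion_mode`, `intensity`.
#' @return Peak data.frame.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mz = "character"))
  need <- c("peak_id", "mz", "rt_min", "ion_mode", "intensity")
  if (!all(need %in% names(df))) {
    stop("peak list must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$mz <- as.numeric(df$mz)
  df
}

#' Write target predictions to TSV
#'
#' @param predictions data.frame (`compound_id`, `target_id`, `score`,
#'   `source`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read target predictions from TSV
#'
#' Accepts the package's own prediction TSV as well as bare database tables
#' with only `compound_id` and `target_id` (score defaults to 1, source to
#' `"database"`).
#'
#' @param path File path.
#' @return Prediction data.frame.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "target_id") %in% names(df))) {
    stop("prediction file must have compound_id and target_id columns",
         call. = FALSE)
  }
  normalize_predictions(df, "database")
}

#' Write a PPI graph as a STRING-style edge TSV
#'
#' @param g An igraph graph; missing `combined_score` attributes default
#'   to 999.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(g, path) {
  e <- igraph::as_edgelist(g)
  score <- igraph::E(g)$combined_score
  if (is.null(score)) score <- rep(999L, nrow(e))
  utils::write.table(
    data.frame(protein1 = e[, 1L], protein2 = e[, 2L], combined_score = score,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a term database as a GMT file
#'
#' Standard GMT: one term per line, tab-separated id, description, then
#' gene ids. The functional-group label is carried inside the description
#' field as `name|group`.
#'
#' @param db A `term_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(seq_len(nrow(db$terms)), function(i) {
    paste(c(db$terms$term_id[i],
            paste0(db$terms$term_name[i], "|", db$terms$group[i]),
            db$terms$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT term file
#'
#' @param path GMT file path; descriptions of the form `name|group` populate
#'   the group label, otherwise the group is `"ungrouped"`.
#' @param universe Optional explicit universe; defaults to the union of all
#'   term gene sets.
#' @return A `term_db`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): fewer than 3 fields", call. = FALSE)
  term_id <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, `[`, "", 2L)
  has_group <- grepl("|", desc, fixed = TRUE)
  term_name <- ifelse(has_group, sub("\\|[^|]*$", "", desc), desc)
  group <- ifelse(has_group, sub("^.*\\|", "", desc), "ungrouped")
  genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (anyDuplicated(term_id)) stop("duplicate term ids in GMT", call. = FALSE)
  if (is.null(universe)) universe <- sort(unique(unlist(genes)))
  terms <- data.frame(term_id = term_id, term_name = term_name, group = group,
                      stringsAsFactors = FALSE)
  terms$genes <- genes
  structure(list(terms = terms, universe = universe), class = "term_db")
}

#' Write a planted-truth record as JSON
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a planted-truth JSON record
#'
#' @param path Path written by [write_planted_truth()].
#' @return A `planted_truth`.
#' @export
read_planted_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_planted_truth(
    true_pairs = x$true_pairs,
    true_peak_assignments = x$true_peak_assignments,
    planted_module_nodes = x$planted_module_nodes,
    planted_term_ids = x$planted_term_ids,
    study_set = x$study_set
  )
}
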