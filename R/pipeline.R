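# Pipeline orchestration: a flat key=value configuration file drives the
# simulate -> predict -> annotate -> network -> ppi -> enrich flow, writing
# every stage artifact plus a consolidated report.json. Defaults reproduce
# the study's printed settings: similarity threshold 0.4, degree threshold
# 17, mass tolerance 5.0 ppm.

pipeline_defaults <- function() {
  list(
    preset = "paper_scale",
    seed = 1L,
    similarity_threshold = 0.4,
    degree_threshold = 17L,
    ppm_tolerance = 5.0,
    alpha = 0.05,
    correction = "BH",
    n_perm = 199L,
    top_k = 10L,
    n_compounds = NA_integer_,
    fp_length = NA_integer_,
    bit_density = NA_real_,
    n_targets = NA_integer_,
    ligands_per_target = NA_integer_,
    n_true_associations = NA_integer_,
    mutation_rate = NA_real_,
    ppm_noise_sd = NA_real_,
    n_decoy_peaks = NA_integer_,
    ppi_n_nodes = NA_integer_,
    ppi_edge_prob = NA_real_,
    planted_module_size = NA_integer_,
    planted_module_density = NA_real_,
    universe_size = NA_integer_,
    n_terms = NA_integer_,
    term_size_min = NA_integer_,
    term_size_max = NA_integer_,
    n_groups = NA_integer_
  )
}

#' Validate a pipeline configuration file
#'
#' Parses a flat `key = value` text file (`#` comments and blank lines
#' allowed), applies defaults, and type/range-checks every entry. Unknown
#' keys are rejected so typos cannot silently fall back to defaults. An
#' empty file yields the all-defaults configuration (similarity threshold
#' 0.4, degree threshold 17, mass tolerance 5.0 ppm).
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @return A validated named list of class `pipeline_config`.
#' @export
validate_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        stop("malformed config line (expected key = value): ", ln, call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg)) {
        stop("unknown config key: ", key, call. = FALSE)
      }
      cfg[[key]] <- parse_config_value(key, val, cfg[[key]])
    }
  }
  chk <- function(ok, msg) if (!ok) stop("config error: ", msg, call. = FALSE)
  chk(cfg$similarity_threshold >= 0 && cfg$similarity_threshold <= 1,
      "similarity_threshold must lie in [0,1]")
  chk(cfg$degree_threshold >= 0, "degree_threshold must be >= 0")
  chk(cfg$ppm_tolerance >= 0, "ppm_tolerance must be >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0,1)")
  chk(cfg$correction %in% c("BH", "bh", "bonferroni"),
      "correction must be BH or bonferroni")
  cfg$correction <- if (tolower(cfg$correction) == "bh") "BH" else "bonferroni"
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

parse_config_value <- function(key, val, default) {
  if (is.character(default)) return(val)
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop("config error: non-numeric value for ", key, call. = FALSE)
  if (is.integer(default)) {
    if (num != round(num)) stop("config error: ", key, " must be an integer", call. = FALSE)
    return(as.integer(num))
  }
  num
}

# Materialize the sim_config behind a pipeline config: preset values first,
# then any explicit per-field overrides from the config file.
pipeline_sim_config <- function(cfg) {
  base <- sim_config(seed = cfg$seed, preset = cfg$preset)
  override <- c("n_compounds", "fp_length", "bit_density", "n_targets",
                "ligands_per_target", "n_true_associations", "mutation_rate",
                "ppm_noise_sd", "n_decoy_peaks", "ppi_n_nodes", "ppi_edge_prob",
                "planted_module_size", "planted_module_density",
                "universe_size", "n_terms", "n_groups")
  for (f in override) if (!is.na(cfg[[f]])) base[[f]] <- cfg[[f]]
  if (!is.na(cfg$term_size_min)) base$term_size_range[1L] <- cfg$term_size_min
  if (!is.na(cfg$term_size_max)) base$term_size_range[2L] <- cfg$term_size_max
  validate_sim_config(base)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate, predict, annotate, network, PPI and enrichment stages
#' in dependency order, writes every stage artifact under `outdir`, and
#' returns (and writes) a consolidated run report. Identical configuration
#' and seed give identical outputs.
#'
#' @param config A `pipeline_config` (see [validate_pipeline_config()]) or
#'   a path to a configuration file.
#' @param outdir Output directory, created if missing.
#' @param quiet Suppress progress logging.
#' @return The run report, a named list (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- validate_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else pipeline_log

  sim_cfg <- pipeline_sim_config(config)
  log("simulate: seed ", sim_cfg$seed, ", ", sim_cfg$n_compounds, " compounds, ",
      sim_cfg$n_targets, " targets")
  data <- simulate_dataset(sim_cfg)
  write_compound_library(data$library, file.path(outdir, "compound_library.tsv"))
  write_reference_panel(data$panel, file.path(outdir, "reference_panel.tsv"))
  write_peak_list(data$peaks, file.path(outdir, "peaks.csv"))
  write_ppi_edges(data$ppi, file.path(outdir, "ppi_edges.tsv"))
  write_gmt(data$term_db, file.path(outdir, "terms.gmt"))
  write_planted_truth(data$truth, file.path(outdir, "planted_truth.json"))

  log("predict: similarity threshold ", config$similarity_threshold,
      " (study default 0.4)")
  predictions <- predict_targets(data$library, data$panel,
                                 threshold = config$similarity_threshold)
  write_predictions(predictions, file.path(outdir, "predictions.tsv"))
  metrics <- prediction_metrics(predictions, data$truth$true_pairs)

  log("annotate: mass tolerance ", config$ppm_tolerance, " ppm (study default 5.0)")
  matches <- match_peaks(data$peaks, data$library, tol_ppm = config$ppm_tolerance)
  utils::write.table(matches, file.path(outdir, "peak_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log("network: degree threshold ", config$degree_threshold, " (study default 17)")
  net <- build_ct_network(predictions)
  deg <- degree_table(net, "compound")
  core <- filter_core_constituents(deg, config$degree_threshold)
  cats <- gen_category_map(net$target_nodes, seed = config$seed)
  tri <- build_ctd_network(net, cats)
  utils::write.table(deg, file.path(outdir, "compound_degrees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(core, file.path(outdir, "core_constituents.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(net, file.path(outdir, "ct_network.sif"), "SIF")
  export_network(tri, file.path(outdir, "ctd_network.sif"), "SIF")

  log("ppi: permutation enrichment with ", config$n_perm, " permutations")
  ppi_rep <- topology_report(data$ppi, subset = data$truth$planted_module_nodes,
                             k = config$top_k, n_perm = config$n_perm,
                             seed = config$seed)
  utils::write.table(ppi_rep$hubs, file.path(outdir, "ppi_hubs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log("enrich: alpha ", config$alpha, ", correction ", config$correction)
  enr <- ora(data$truth$study_set, data$term_db, alpha = config$alpha,
             correction = config$correction)
  utils::write.table(enr[, setdiff(names(enr), "genes")],
                     file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shares <- group_shares(enr[enr$significant, , drop = FALSE])
  utils::write.table(shares, file.path(outdir, "group_shares.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- network_summary(net)
  tri_summary <- network_summary(tri)
  report <- list(
    software = paste0("serumnetpharm ",
                      as.character(utils::packageVersion("serumnetpharm"))),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      compounds = nrow(data$library$compounds),
      peaks = nrow(data$peaks),
      peaks_matched = length(unique(matches$peak_id)),
      predictions = nrow(predictions),
      ct_nodes = unname(summary[["n_nodes"]]),
      ct_edges = unname(summary[["n_edges"]]),
      ctd_edges = unname(tri_summary[["n_edges"]]),
      core_constituents = nrow(core),
      ppi_nodes = ppi_rep$n_nodes,
      ppi_edges = ppi_rep$n_edges,
      ppi_average_degree = ppi_rep$average_degree,
      ppi_enrichment_p = ppi_rep$enrichment_p,
      significant_terms = sum(enr$significant)
    ),
    planted_recovery = list(
      precision = unname(metrics[["precision"]]),
      recall = unname(metrics[["recall"]])
    )
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
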