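# Simulation configuration: a validated flat list driving every synthetic
# generator. All randomness flows from the single `seed`; each generator
# stage derives its own sub-seed deterministically so stages can be rerun
# independently with identical results.

#' Simulation configuration for the synthetic-data generators
#'
#' Builds and validates the configuration object consumed by
#' [gen_compound_library()], [gen_reference_panel()], [plant_associations()],
#' [gen_peak_list()], [gen_ppi_graph()] and [gen_term_db()]. The
#' `"paper_scale"` preset reproduces the scale of the serum-constituent study
#' the package emulates: 60 compounds, 338 targets, a 91-node PPI graph, and
#' a term database with 8 functional groups.
#'
#' @param seed Integer root seed; identical seed and parameters give
#'   bit-identical outputs.
#' @param n_compounds Number of library compounds.
#' @param fp_length Fingerprint length in bits (>= 8).
#' @param bit_density Probability that any fingerprint bit is set, in (0,1).
#' @param n_targets Number of reference targets.
#' @param ligands_per_target Reference ligands generated per target.
#' @param n_true_associations Number of compounds given a planted target
#'   association (<= `n_compounds`).
#' @param mutation_rate Per-bit flip probability used when deriving planted
#'   compound fingerprints and within-target ligand variants, in [0, 0.5).
#' @param ppm_noise_sd Standard deviation of the multiplicative mass noise on
#'   planted peaks, in ppm.
#' @param n_decoy_peaks Number of unassignable decoy peaks.
#' @param ppi_n_nodes,ppi_edge_prob Erdős–Rényi background for the synthetic
#'   PPI graph.
#' @param planted_module_size,planted_module_density Size and internal edge
#'   density of the dense module planted into the PPI graph.
#' @param universe_size Size of the gene universe behind the term database.
#' @param n_terms Number of annotation terms.
#' @param term_size_range Length-2 integer vector, min and max genes per term.
#' @param n_groups Number of functional group labels over the terms.
#' @param herb_labels Character vector of herb-source labels assigned to
#'   compounds.
#' @param preset Optional preset name; currently only `"paper_scale"`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 30L,
                       fp_length = 1024L,
                       bit_density = 0.1,
                       n_targets = 20L,
                       ligands_per_target = 2L,
                       n_true_associations = min(15L, n_compounds),
                       mutation_rate = 0.02,
                       ppm_noise_sd = 1,
                       n_decoy_peaks = 10L,
                       ppi_n_nodes = 100L,
                       ppi_edge_prob = 0.05,
                       planted_module_size = 15L,
                       planted_module_density = 0.5,
                       universe_size = 1000L,
                       n_terms = 50L,
                       term_size_range = c(10L, 50L),
                       n_groups = 8L,
                       herb_labels = c("BB", "RG", "PL", "PS"),
                       preset = NULL) {
  if (!is.null(preset)) {
    if (!identical(preset, "paper_scale")) {
      stop("unknown preset: ", preset, call. = FALSE)
    }
    n_compounds <- 60L
    fp_length <- 1024L
    bit_density <- 0.1
    n_targets <- 338L
    ligands_per_target <- 2L
    n_true_associations <- 30L
    mutation_rate <- 0.02
    ppm_noise_sd <- 1
    n_decoy_peaks <- 20L
    ppi_n_nodes <- 91L
    ppi_edge_prob <- 448 / choose(91, 2)
    planted_module_size <- 15L
    planted_module_density <- 0.5
    universe_size <- 1000L
    n_terms <- 84L
    term_size_range <- c(10L, 50L)
    n_groups <- 8L
  }
  cfg <- list(
    seed = as.integer(seed),
    n_compounds = as.integer(n_compounds),
    fp_length = as.integer(fp_length),
    bit_density = bit_density,
    n_targets = as.integer(n_targets),
    ligands_per_target = as.integer(ligands_per_target),
    n_true_associations = as.integer(n_true_associations),
    mutation_rate = mutation_rate,
    ppm_noise_sd = ppm_noise_sd,
    n_decoy_peaks = as.integer(n_decoy_peaks),
    ppi_n_nodes = as.integer(ppi_n_nodes),
    ppi_edge_prob = ppi_edge_prob,
    planted_module_size = as.integer(planted_module_size),
    planted_module_density = planted_module_density,
    universe_size = as.integer(universe_size),
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    n_groups = as.integer(n_groups),
    herb_labels = as.character(herb_labels)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` list.
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  counts <- c("n_compounds", "n_targets", "ligands_per_target",
              "n_true_associations", "n_decoy_peaks", "ppi_n_nodes",
              "planted_module_size", "universe_size", "n_terms", "n_groups")
  for (f in counts) {
    chk(!is.na(cfg[[f]]) && cfg[[f]] >= 0L, paste(f, "must be a non-negative count"))
  }
  chk(cfg$fp_length >= 8L, "fp_length must be >= 8")
  chk(cfg$bit_density > 0 && cfg$bit_density < 1, "bit_density must lie in (0,1)")
  chk(cfg$mutation_rate >= 0 && cfg$mutation_rate < 0.5,
      "mutation_rate must lie in [0, 0.5): similarity is not recoverable beyond")
  chk(cfg$ppm_noise_sd >= 0, "ppm_noise_sd must be >= 0")
  chk(cfg$ppi_edge_prob >= 0 && cfg$ppi_edge_prob <= 1, "ppi_edge_prob must lie in [0,1]")
  chk(cfg$planted_module_density >= 0 && cfg$planted_module_density <= 1,
      "planted_module_density must lie in [0,1]")
  chk(cfg$planted_module_size <= cfg$ppi_n_nodes,
      "planted_module_size must not exceed ppi_n_nodes")
  chk(cfg$n_true_associations <= cfg$n_compounds,
      "n_true_associations must not exceed n_compounds")
  chk(length(cfg$term_size_range) == 2L && cfg$term_size_range[1L] <= cfg$term_size_range[2L],
      "term_size_range must be an ordered pair")
  chk(cfg$term_size_range[2L] <= cfg$universe_size,
      "term sizes must not exceed universe_size")
  invisible(cfg)
}

# Deterministic per-stage sub-seed derived from the root seed. Kept below
# 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  offsets <- c(library = 11L, panel = 23L, plant = 37L, peaks = 41L,
               ppi = 53L, terms = 67L, predictions = 71L, categories = 83L,
               decoys = 89L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) %% 20000000 + 1) * 101 + offsets[[stage]])
}

# Evaluate `expr` under a locally set RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
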