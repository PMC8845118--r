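# Seeded synthetic-data generators. Every generator derives its own
# sub-seed from the root seed so the full dataset, or any single stage, is
# bit-reproducible. Each generator that hides structure in the data returns
# the planted ground truth alongside it.

#' Generate a synthetic compound library
#'
#' Emulates a panel of serum constituents of a multi-herb decoction: each
#' compound carries a herb-source label, a neutral monoisotopic mass drawn
#' uniformly on \[50, 1500\] Da (the instrument scan range), and an
#' independent-Bernoulli binary fingerprint.
#'
#' @param config A [sim_config()].
#' @return An object of class `compound_library`: a list with `compounds`
#'   (data.frame of `compound_id`, `name`, `herb`, `neutral_mass`) and
#'   `fingerprints` (0/1 matrix, one row per compound).
#' @export
gen_compound_library <- function(config) {
  validate_sim_config(config)
  n <- config$n_compounds
  with_seed(stage_seed(config$seed, "library"), {
    ids <- sprintf("CPD%03d", seq_len(n))
    herbs <- if (n > 0L) {
      sample(config$herb_labels, n, replace = TRUE)
    } else character()
    compounds <- data.frame(
      compound_id = ids,
      name = sprintf("constituent-%03d", seq_len(n)),
      herb = herbs,
      neutral_mass = if (n > 0L) stats::runif(n, 50, 1500) else numeric(),
      stringsAsFactors = FALSE
    )
    fps <- matrix(
      stats::rbinom(n * config$fp_length, 1L, config$bit_density),
      nrow = n, ncol = config$fp_length,
      dimnames = list(ids, NULL)
    )
    structure(list(compounds = compounds, fingerprints = fps),
              class = "compound_library")
  })
}

#' Generate a synthetic reference ligand-target panel
#'
#' Stands in for ligand panels collected from drug databases or pathway
#' inhibitors: each target gets a random prototype fingerprint, and its
#' ligands are per-bit mutated copies of it, so within-target similarity is
#' high and between-target similarity is at the random-background level.
#'
#' @param config A [sim_config()].
#' @return An object of class `reference_panel`: a list with `ligands`
#'   (data.frame of `ligand_id`, `target_id`) and `fingerprints` (0/1
#'   matrix, one row per ligand).
#' @export
gen_reference_panel <- function(config) {
  validate_sim_config(config)
  if (config$n_targets < 1L || config$ligands_per_target < 1L) {
    stop("panel generation needs n_targets >= 1 and ligands_per_target >= 1",
         call. = FALSE)
  }
  nt <- config$n_targets
  lpt <- config$ligands_per_target
  with_seed(stage_seed(config$seed, "panel"), {
    targets <- sprintf("TGT%03d", seq_len(nt))
    prototypes <- matrix(
      stats::rbinom(nt * config$fp_length, 1L, config$bit_density),
      nrow = nt, ncol = config$fp_length
    )
    n_lig <- nt * lpt
    lig_target_idx <- rep(seq_len(nt), each = lpt)
    flips <- matrix(
      stats::rbinom(n_lig * config$fp_length, 1L, config$mutation_rate),
      nrow = n_lig, ncol = config$fp_length
    )
    fps <- abs(prototypes[lig_target_idx, , drop = FALSE] - flips)
    ids <- sprintf("LIG%04d", seq_len(n_lig))
    rownames(fps) <- ids
    ligands <- data.frame(
      ligand_id = ids,
      target_id = targets[lig_target_idx],
      stringsAsFactors = FALSE
    )
    structure(list(ligands = ligands, fingerprints = fps),
              class = "reference_panel")
  })
}

#' Plant recoverable compound-target associations
#'
#' Replaces the fingerprints of `n_true_associations` randomly chosen
#' compounds with bit-mutated copies (each bit flipped independently with
#' probability `mutation_rate`) of a randomly chosen reference ligand, and
#' records the (compound, target) pairs as ground truth. With a low mutation
#' rate these pairs score far above the similarity threshold while
#' unplanted compounds stay at background similarity.
#'
#' @param library A `compound_library`.
#' @param panel A `reference_panel` with the same fingerprint length.
#' @param config A [sim_config()].
#' @return A list with `library` (modified copy) and `truth` (a
#'   `planted_truth` whose `true_pairs` data.frame holds the planted
#'   compound-target pairs).
#' @export
plant_associations <- function(library, panel, config) {
  validate_sim_config(config)
  stopifnot(inherits(library, "compound_library"), inherits(panel, "reference_panel"))
  if (ncol(library$fingerprints) != ncol(panel$fingerprints)) {
    stop("library and panel fingerprint lengths differ", call. = FALSE)
  }
  k <- config$n_true_associations
  if (k > nrow(library$compounds)) {
    stop("n_true_associations exceeds library size", call. = FALSE)
  }
  with_seed(stage_seed(config$seed, "plant"), {
    truth_pairs <- data.frame(compound_id = character(), target_id = character(),
                              stringsAsFactors = FALSE)
    if (k > 0L) {
      chosen <- sort(sample.int(nrow(library$compounds), k))
      lig_idx <- sample.int(nrow(panel$ligands), k, replace = TRUE)
      flips <- matrix(
        stats::rbinom(k * ncol(panel$fingerprints), 1L, config$mutation_rate),
        nrow = k
      )
      library$fingerprints[chosen, ] <-
        abs(panel$fingerprints[lig_idx, , drop = FALSE] - flips)
      truth_pairs <- data.frame(
        compound_id = library$compounds$compound_id[chosen],
        target_id = panel$ligands$target_id[lig_idx],
        stringsAsFactors = FALSE
      )
    }
    list(library = library, truth = new_planted_truth(true_pairs = truth_pairs))
  })
}

#' Generate a synthetic MS1 peak list with planted assignments
#'
#' Emits one peak per (compound, adduct) with
#' `mz = adduct_mz(mass, adduct) * (1 + eps/1e6)`, `eps ~ Normal(0,
#' ppm_noise_sd)`, plus `n_decoy_peaks` uniform-random decoy peaks kept at
#' least 20 ppm away from every library adduct mass so they can never be
#' annotated at the default tolerance.
#'
#' @param library A `compound_library`.
#' @param config A [sim_config()].
#' @param adducts Adduct rule table, default [default_adducts()].
#' @return A list with `peaks` (data.frame `peak_id`, `mz`, `rt_min`,
#'   `ion_mode`, `intensity`) and `truth` (a `planted_truth` whose
#'   `true_peak_assignments` maps planted peak ids to (compound, adduct)).
#' @export
gen_peak_list <- function(library, config, adducts = default_adducts()) {
  validate_sim_config(config)
  stopifnot(inherits(library, "compound_library"))
  with_seed(stage_seed(config$seed, "peaks"), {
    n_cpd <- nrow(library$compounds)
    planted <- NULL
    if (n_cpd > 0L) {
      grid <- expand.grid(ci = seq_len(n_cpd), ai = seq_len(nrow(adducts)))
      grid <- grid[order(grid$ci, grid$ai), , drop = FALSE]
      theo <- mapply(function(ci, ai) {
        adduct_mz(library$compounds$neutral_mass[ci], adducts[ai, ])
      }, grid$ci, grid$ai)
      eps <- stats::rnorm(length(theo), 0, config$ppm_noise_sd)
      planted <- data.frame(
        compound_id = library$compounds$compound_id[grid$ci],
        adduct = adducts$name[grid$ai],
        mz = theo * (1 + eps / 1e6),
        ion_mode = adducts$polarity[grid$ai],
        stringsAsFactors = FALSE
      )
    }
    all_theo <- if (n_cpd > 0L) {
      unlist(lapply(seq_len(nrow(adducts)), function(ai) {
        vapply(library$compounds$neutral_mass, adduct_mz, numeric(1), adducts[ai, ])
      }))
    } else numeric()
    decoys <- gen_decoy_mz(config$n_decoy_peaks, all_theo, min_ppm = 20)
    n_planted <- if (is.null(planted)) 0L else nrow(planted)
    n_total <- n_planted + length(decoys)
    ids <- sprintf("PK%04d", seq_len(n_total))
    peaks <- data.frame(
      peak_id = ids,
      mz = c(if (n_planted) planted$mz, decoys),
      rt_min = if (n_total) stats::runif(n_total, 0, 50) else numeric(),
      ion_mode = c(if (n_planted) planted$ion_mode,
                   rep_len(c("negative", "positive"), length(decoys))),
      intensity = if (n_total) round(stats::rlnorm(n_total, 10, 1), 1) else numeric(),
      stringsAsFactors = FALSE
    )
    assignments <- if (n_planted) {
      data.frame(peak_id = ids[seq_len(n_planted)],
                 compound_id = planted$compound_id,
                 adduct = planted$adduct,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(peak_id = character(), compound_id = character(),
                 adduct = character(), stringsAsFactors = FALSE)
    }
    list(peaks = peaks, truth = new_planted_truth(true_peak_assignments = assignments))
  })
}

# Rejection-sample decoy m/z values uniform on [50, 1500] at least `min_ppm`
# from every theoretical library adduct mass.
gen_decoy_mz <- function(n, theoretical, min_ppm = 20) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n - length(out), 50, 1500)
    ok <- vapply(cand, function(mz) {
      length(theoretical) == 0L ||
        min(abs(mz - theoretical) / theoretical) * 1e6 >= min_ppm
    }, logical(1))
    out <- c(out, cand[ok])
  }
  out
}

#' Generate a synthetic PPI graph with a planted dense module
#'
#' Draws an Erdős–Rényi background at `ppi_edge_prob`, then adds edges
#' among a random set of `planted_module_size` nodes until the module's
#' internal density reaches `planted_module_density`. The result is a
#' simple undirected graph.
#'
#' @param config A [sim_config()].
#' @return A list with `graph` (an [igraph][igraph::aaa-igraph-package]
#'   object) and `truth` (a `planted_truth` carrying
#'   `planted_module_nodes`).
#' @export
gen_ppi_graph <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "ppi"), {
    n <- config$ppi_n_nodes
    nodes <- sprintf("PRT%03d", seq_len(n))
    g <- igraph::sample_gnp(n, config$ppi_edge_prob, directed = FALSE)
    igraph::V(g)$name <- nodes
    m <- config$planted_module_size
    module <- character()
    if (m >= 2L) {
      module <- sort(sample(nodes, m))
      pairs <- utils::combn(module, 2L)
      want <- ceiling(config$planted_module_density * ncol(pairs))
      has <- apply(pairs, 2L, function(p) igraph::are_adjacent(g, p[1L], p[2L]))
      need <- want - sum(has)
      if (need > 0L) {
        missing_idx <- which(!has)
        add <- missing_idx[sample.int(length(missing_idx), need)]
        g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
      }
    } else if (m == 1L) {
      module <- sort(sample(nodes, 1L))
    }
    g <- igraph::simplify(g)
    list(graph = g, truth = new_planted_truth(planted_module_nodes = module))
  })
}

#' Generate a synthetic term database with one planted enriched term
#'
#' Draws `n_terms` gene sets from a universe of `universe_size` ids, assigns
#' each a functional-group label, and constructs one planted term whose
#' genes are drawn entirely from a designated study set so that
#' over-representation analysis must rank it first.
#'
#' @param config A [sim_config()].
#' @param study_set Optional character vector of universe genes used as the
#'   designated study set; by default a seeded random subset of size
#'   `min(50, universe_size %/% 10)` (at least 10 where possible).
#' @return A list with `db` (a `term_db`: list of `terms` data.frame
#'   (`term_id`, `term_name`, `group`, and list-column `genes`) and
#'   `universe`) and `truth` (a `planted_truth` carrying `planted_term_ids`
#'   and `study_set`).
#' @export
gen_term_db <- function(config, study_set = NULL) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "terms"), {
    universe <- sprintf("GENE%04d", seq_len(config$universe_size))
    if (is.null(study_set)) {
      sz <- min(50L, max(min(10L, config$universe_size), config$universe_size %/% 10L))
      study_set <- sort(sample(universe, sz))
    } else {
      if (!all(study_set %in% universe)) {
        stop("study_set must be a subset of the generated universe", call. = FALSE)
      }
    }
    nt <- config$n_terms
    groups <- sprintf("group%02d", seq_len(max(config$n_groups, 1L)))
    terms <- data.frame(
      term_id = sprintf("TERM%04d", seq_len(nt)),
      term_name = sprintf("synthetic term %04d", seq_len(nt)),
      group = if (nt > 0L) sample(groups, nt, replace = TRUE) else character(),
      stringsAsFactors = FALSE
    )
    sizes <- if (nt > 0L) {
      sample(seq(config$term_size_range[1L], config$term_size_range[2L]), nt,
             replace = TRUE)
    } else integer()
    genes <- lapply(sizes, function(s) sort(sample(universe, s)))
    planted_ids <- character()
    if (nt > 0L && length(study_set) > 0L) {
      k <- min(length(study_set), config$term_size_range[2L])
      k <- max(k, min(config$term_size_range[1L], length(study_set)))
      genes[[1L]] <- sort(sample(study_set, k))
      terms$term_name[1L] <- "planted enriched term"
      planted_ids <- terms$term_id[1L]
    }
    terms$genes <- genes
    db <- structure(list(terms = terms, universe = universe), class = "term_db")
    list(db = db,
         truth = new_planted_truth(planted_term_ids = planted_ids,
                                   study_set = study_set))
  })
}

#' Construct a planted-truth record
#'
#' @param true_pairs data.frame of planted (compound_id, target_id) pairs.
#' @param true_peak_assignments data.frame mapping peak_id to
#'   (compound_id, adduct).
#' @param planted_module_nodes Character vector of PPI module node ids.
#' @param planted_term_ids Character vector of planted term ids.
#' @param study_set Character vector, the designated ORA study set.
#' @return A list of class `planted_truth`.
#' @export
new_planted_truth <- function(true_pairs = NULL, true_peak_assignments = NULL,
                              planted_module_nodes = NULL,
                              planted_term_ids = NULL, study_set = NULL) {
  structure(list(
    true_pairs = true_pairs,
    true_peak_assignments = true_peak_assignments,
    planted_module_nodes = planted_module_nodes,
    planted_term_ids = planted_term_ids,
    study_set = study_set
  ), class = "planted_truth")
}

#' Generate the full synthetic dataset for one configuration
#'
#' Runs every generator in dependency order and merges the planted truths.
#'
#' @param config A [sim_config()].
#' @return A list with `library`, `panel`, `peaks`, `ppi`, `term_db` and a
#'   merged `truth`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  library <- gen_compound_library(config)
  panel <- gen_reference_panel(config)
  planted <- plant_associations(library, panel, config)
  library <- planted$library
  pk <- gen_peak_list(library, config)
  ppi <- gen_ppi_graph(config)
  tdb <- gen_term_db(config)
  truth <- new_planted_truth(
    true_pairs = planted$truth$true_pairs,
    true_peak_assignments = pk$truth$true_peak_assignments,
    planted_module_nodes = ppi$truth$planted_module_nodes,
    planted_term_ids = tdb$truth$planted_term_ids,
    study_set = tdb$truth$study_set
  )
  list(library = library, panel = panel, peaks = pk$peaks,
       ppi = ppi$graph, term_db = tdb$db, truth = truth)
}
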