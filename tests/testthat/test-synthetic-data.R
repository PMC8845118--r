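test_that("sim_config validates fields and rejects bad values", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_compounds = -1), "non-negative")
  expect_error(sim_config(fp_length = 4), "fp_length")
  expect_error(sim_config(bit_density = 0), "bit_density")
  expect_error(sim_config(mutation_rate = 0.5), "mutation_rate")
  expect_error(sim_config(ppi_edge_prob = 1.5), "ppi_edge_prob")
  expect_error(sim_config(planted_module_size = 20, ppi_n_nodes = 10),
               "planted_module_size")
  expect_error(sim_config(n_true_associations = 50, n_compounds = 10),
               "n_true_associations")
  expect_error(sim_config(term_size_range = c(10, 5)), "ordered pair")
})

test_that("paper_scale preset reproduces the study scale", {
  cfg <- sim_config(seed = 1, preset = "paper_scale")
  expect_identical(cfg$n_compounds, 60L)
  expect_identical(cfg$n_targets, 338L)
  expect_identical(cfg$ppi_n_nodes, 91L)
  lib <- gen_compound_library(cfg)
  expect_identical(nrow(lib$compounds), 60L)
})

test_that("compound library generation honours config and determinism", {
  cfg <- sim_config(seed = 1, n_compounds = 0)
  expect_identical(nrow(gen_compound_library(cfg)$compounds), 0L)

  cfg <- sim_config(seed = 1, n_compounds = 25, fp_length = 64)
  a <- gen_compound_library(cfg)
  b <- gen_compound_library(cfg)
  expect_identical(a, b)
  expect_identical(dim(a$fingerprints), c(25L, 64L))
  expect_true(all(a$compounds$neutral_mass >= 50 & a$compounds$neutral_mass <= 1500))
  expect_true(all(a$compounds$herb %in% c("BB", "RG", "PL", "PS")))
})

test_that("fingerprint popcount matches binomial moments", {
  cfg <- sim_config(seed = 42, n_compounds = 1000, fp_length = 1024,
                    bit_density = 0.1)
  lib <- gen_compound_library(cfg)
  popcounts <- rowSums(lib$fingerprints)
  se <- sqrt(1024 * 0.1 * 0.9 / 1000)
  expect_lt(abs(mean(popcounts) - 102.4), 3 * se)
})

test_that("reference panel has the right shape and within-target structure", {
  cfg <- sim_config(seed = 2, n_targets = 2, ligands_per_target = 3,
                    fp_length = 256, mutation_rate = 0.02)
  p <- gen_reference_panel(cfg)
  expect_identical(nrow(p$ligands), 6L)
  expect_identical(length(unique(p$ligands$target_id)), 2L)
  expect_identical(p, gen_reference_panel(cfg))

  # within-target similarity exceeds between-target similarity
  s <- tanimoto_matrix(p$fingerprints, p$fingerprints)
  same <- outer(p$ligands$target_id, p$ligands$target_id, "==")
  diag(same) <- NA
  within <- mean(s[which(same)])
  between <- s[which(!same)]
  expect_true(all(between < within))
})

test_that("planted associations are recorded and recoverable", {
  cfg <- sim_config(seed = 3, n_compounds = 10, n_true_associations = 0)
  lib <- gen_compound_library(cfg)
  pan <- gen_reference_panel(cfg)
  res <- plant_associations(lib, pan, cfg)
  expect_identical(nrow(res$truth$true_pairs), 0L)

  # zero mutation: planted fingerprint equals its parent ligand exactly
  cfg0 <- sim_config(seed = 4, n_compounds = 6, n_true_associations = 6,
                     mutation_rate = 0, fp_length = 128)
  lib0 <- gen_compound_library(cfg0)
  pan0 <- gen_reference_panel(cfg0)
  res0 <- plant_associations(lib0, pan0, cfg0)
  for (i in seq_len(nrow(res0$truth$true_pairs))) {
    cid <- res0$truth$true_pairs$compound_id[i]
    tid <- res0$truth$true_pairs$target_id[i]
    ligs <- pan0$fingerprints[pan0$ligands$target_id == tid, , drop = FALSE]
    best <- max(tanimoto_matrix(res0$library$fingerprints[cid, , drop = FALSE], ligs))
    expect_identical(best, 1)
  }
})

test_that("mean Tanimoto of planted pairs stays high at low mutation rates", {
  # Monte-Carlo over the stated generator: fp 2048, density 0.1, rate 0.02
  sims <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, n_compounds = 2, n_true_associations = 2,
                      fp_length = 2048, bit_density = 0.1,
                      mutation_rate = 0.02, n_targets = 2,
                      ligands_per_target = 1)
    lib <- gen_compound_library(cfg)
    pan <- gen_reference_panel(cfg)
    res <- plant_associations(lib, pan, cfg)
    pairs <- res$truth$true_pairs
    mean(vapply(seq_len(nrow(pairs)), function(i) {
      ligs <- pan$fingerprints[pan$ligands$target_id == pairs$target_id[i], ,
                               drop = FALSE]
      max(tanimoto_matrix(
        res$library$fingerprints[pairs$compound_id[i], , drop = FALSE], ligs))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(sims), 0.6)
})

test_that("peak list generation plants assignable peaks and inert decoys", {
  # noiseless: every planted peak matches its compound at 0 ppm
  cfg <- sim_config(seed = 5, n_compounds = 4, ppm_noise_sd = 0,
                    n_decoy_peaks = 0)
  lib <- gen_compound_library(cfg)
  pk <- gen_peak_list(lib, cfg)
  expect_identical(nrow(pk$peaks), 8L) # 4 compounds x 2 adducts
  m <- match_peaks(pk$peaks, lib, tol_ppm = 0.001)
  joined <- merge(pk$truth$true_peak_assignments, m,
                  by = c("peak_id", "compound_id", "adduct"))
  expect_identical(nrow(joined), 8L)
  expect_true(all(joined$ppm_error < 1e-6))

  # decoys only: empty library still yields the decoy peaks
  cfg2 <- sim_config(seed = 6, n_compounds = 0, n_decoy_peaks = 5)
  lib2 <- gen_compound_library(cfg2)
  pk2 <- gen_peak_list(lib2, cfg2)
  expect_identical(nrow(pk2$peaks), 5L)
  expect_identical(nrow(pk2$truth$true_peak_assignments), 0L)

  # empty everything
  cfg3 <- sim_config(seed = 7, n_compounds = 0, n_decoy_peaks = 0)
  pk3 <- gen_peak_list(gen_compound_library(cfg3), cfg3)
  expect_identical(nrow(pk3$peaks), 0L)
})

test_that("decoy peaks stay at least 20 ppm from every library adduct", {
  cfg <- sim_config(seed = 8, n_compounds = 10, n_decoy_peaks = 30)
  lib <- gen_compound_library(cfg)
  pk <- gen_peak_list(lib, cfg)
  decoys <- pk$peaks[!pk$peaks$peak_id %in% pk$truth$true_peak_assignments$peak_id, ]
  theo <- c(lib$compounds$neutral_mass + 1.007276466,
            lib$compounds$neutral_mass - 1.007276466)
  for (mz in decoys$mz) {
    expect_gte(min(abs(mz - theo) / theo) * 1e6, 20)
  }
})

test_that("PPI generator plants a dense module on an ER background", {
  # degenerate: no background, complete module
  cfg <- sim_config(seed = 9, ppi_n_nodes = 20, ppi_edge_prob = 0,
                    planted_module_size = 6, planted_module_density = 1)
  res <- gen_ppi_graph(cfg)
  expect_equal(igraph::ecount(res$graph), 15) # 6*5/2
  expect_identical(length(res$truth$planted_module_nodes), 6L)

  # pure ER when module size is 0; edge count near binomial expectation
  counts <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, ppi_n_nodes = 100, ppi_edge_prob = 0.05,
                      planted_module_size = 0)
    igraph::ecount(gen_ppi_graph(cfg)$graph)
  }, numeric(1))
  sd_edges <- sqrt(choose(100, 2) * 0.05 * 0.95)
  expect_lt(abs(mean(counts) - 247.5), 4 * sd_edges)

  # graphs are simple
  g <- gen_ppi_graph(sim_config(seed = 10))$graph
  expect_true(igraph::is_simple(g))
})

test_that("term database plants one extreme term and respects the universe", {
  cfg <- sim_config(seed = 11, n_terms = 0)
  res <- gen_term_db(cfg)
  expect_identical(nrow(res$db$terms), 0L)

  cfg <- sim_config(seed = 12, universe_size = 1000, n_terms = 40,
                    term_size_range = c(10, 40))
  res <- gen_term_db(cfg)
  expect_true(all(unlist(res$db$terms$genes) %in% res$db$universe))
  expect_identical(length(res$truth$planted_term_ids), 1L)

  enr <- ora(res$truth$study_set, res$db)
  expect_identical(enr$term_id[1], res$truth$planted_term_ids)
  expect_lt(enr$p[1], 1e-20)
})

test_that("the full dataset is bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 99, n_compounds = 8, n_targets = 4,
                    n_true_associations = 4, fp_length = 64,
                    ppi_n_nodes = 30, n_terms = 10, universe_size = 100,
                    term_size_range = c(5, 20))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$library, b$library)
  expect_identical(a$peaks, b$peaks)
  expect_identical(igraph::as_edgelist(a$ppi), igraph::as_edgelist(b$ppi))
  expect_identical(a$term_db, b$term_db)
  expect_identical(a$truth, b$truth)
})
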