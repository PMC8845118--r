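test_that("adduct m/z arithmetic uses the proton-transfer convention", {
  add <- default_adducts()
  pos <- add[add$name == "[M+H]+", ]
  neg <- add[add$name == "[M-H]-", ]
  expect_equal(adduct_mz(100, pos), 101.007276466)
  expect_equal(adduct_mz(100, neg), 98.992723534)
  neutral <- data.frame(name = "[M]", mass_shift = 0, polarity = "positive",
                        charge = 1L)
  expect_equal(adduct_mz(250.5, neutral), 250.5)
  expect_error(adduct_mz(-1, pos), "positive")
  expect_error(adduct_mz(0.5, neg), "non-positive")
})

test_that("ppm_error is the standard relative deviation", {
  expect_identical(ppm_error(500, 500), 0)
  expect_equal(ppm_error(500.0025, 500), 5.0)
  expect_equal(ppm_error(179.056112, 179.057902),
               0.001790 / 179.057902 * 1e6, tolerance = 1e-9)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("match_peaks annotates the glucose [M-H]- ion", {
  lib <- make_library(GLUCOSE_MASS, ids = "glc")
  peaks <- data.frame(peak_id = "p1", mz = GLUCOSE_MASS - 1.007276466,
                      rt_min = 1, ion_mode = "negative", intensity = 100,
                      stringsAsFactors = FALSE)
  m <- match_peaks(peaks, lib, tol_ppm = 5)
  expect_identical(nrow(m), 1L)
  expect_identical(m$adduct, "[M-H]-")
  expect_lt(m$ppm_error, 1e-9)

  # a 10 ppm shift falls outside the 5 ppm window
  peaks$mz <- peaks$mz * (1 + 10e-6)
  expect_identical(nrow(match_peaks(peaks, lib, tol_ppm = 5)), 0L)
  # but inside a 12 ppm window
  expect_identical(nrow(match_peaks(peaks, lib, tol_ppm = 12)), 1L)
})

test_that("match_peaks respects ion mode and rejects unknown labels", {
  lib <- make_library(c(200, 300))
  peaks <- data.frame(peak_id = "p1", mz = 201.007276466, rt_min = 1,
                      ion_mode = "negative", intensity = 1,
                      stringsAsFactors = FALSE)
  # the m/z fits [M+H]+ of the 200 Da compound but the mode is negative
  expect_identical(nrow(match_peaks(peaks, lib)), 0L)
  peaks$ion_mode <- "positive"
  expect_identical(nrow(match_peaks(peaks, lib)), 1L)
  peaks$ion_mode <- "Negative"
  expect_error(match_peaks(peaks, lib), "ion_mode")
  expect_identical(nrow(match_peaks(peaks[0, ], lib)), 0L)
})

test_that("the match set grows monotonically with tolerance", {
  cfg <- sim_config(seed = 14, n_compounds = 15, ppm_noise_sd = 3,
                    n_decoy_peaks = 10)
  lib <- gen_compound_library(cfg)
  pk <- gen_peak_list(lib, cfg)
  prev <- NULL
  for (tol in c(0.5, 1, 2, 5, 10)) {
    m <- match_peaks(pk$peaks, lib, tol_ppm = tol)
    key <- paste(m$peak_id, m$compound_id, m$adduct)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("noiseless peak round trip has perfect recall and precision", {
  cfg <- sim_config(seed = 15, n_compounds = 25, ppm_noise_sd = 0,
                    n_decoy_peaks = 15)
  lib <- gen_compound_library(cfg)
  pk <- gen_peak_list(lib, cfg)
  m <- match_peaks(pk$peaks, lib, tol_ppm = 5)
  truth <- pk$truth$true_peak_assignments
  got <- unique(paste(m$peak_id, m$compound_id, m$adduct))
  want <- paste(truth$peak_id, truth$compound_id, truth$adduct)
  # every planted assignment recovered
  expect_true(all(want %in% got))
  # every planted peak's best (first) match is the planted compound
  best <- m[!duplicated(m$peak_id), ]
  best <- best[best$peak_id %in% truth$peak_id, ]
  joined <- merge(best, truth, by = "peak_id")
  expect_true(all(joined$compound_id.x == joined$compound_id.y))
  # no decoy peak is ever matched
  decoy_ids <- setdiff(pk$peaks$peak_id, truth$peak_id)
  expect_false(any(m$peak_id %in% decoy_ids))
})

test_that("RDBE matches hand-computed values for textbook formulas", {
  # methane, ethane, benzene, glucose, aspirin, caffeine, pyridine,
  # acetonitrile, urea, cysteine
  expect_equal(rdbe(1, 4), 0)
  expect_equal(rdbe(2, 6), 0)
  expect_equal(rdbe(6, 6), 4)
  expect_equal(rdbe(6, 12), 1)
  expect_equal(rdbe(9, 8), 6)
  expect_equal(rdbe(8, 10, 4), 6)
  expect_equal(rdbe(5, 5, 1), 4)
  expect_equal(rdbe(2, 3, 1), 2)
  expect_equal(rdbe(1, 4, 2), 1)
  expect_equal(rdbe(3, 7, 1), 1)
  # CH5 is impossible: half-integer negative RDBE
  expect_equal(rdbe(1, 5), -0.5)
})

test_that("formula enumeration finds glucose and obeys the filters", {
  neg <- default_adducts()[2, ]
  mz <- GLUCOSE_MASS - 1.007276466
  b <- element_bounds(C = c(0, 10), H = c(0, 20), N = c(0, 0), O = c(0, 10),
                      S = c(0, 0))
  res <- enumerate_formulas(mz, neg, tol_ppm = 5, bounds = b)
  expect_true("C6H12O6" %in% res$formula)
  hit <- res[res$formula == "C6H12O6", ]
  expect_lt(hit$ppm_error, 1e-6)
  expect_equal(hit$rdbe, 1)
  # all candidates obey tolerance, RDBE and parity
  expect_true(all(res$ppm_error <= 5))
  expect_true(all(res$rdbe >= 0))
  expect_true(all(abs(res$rdbe - round(res$rdbe)) < 1e-9))
  # sorted by ppm error
  expect_true(!is.unsorted(res$ppm_error))
})

test_that("zero tolerance with an unrepresentable mass yields no candidates", {
  pos <- default_adducts()[1, ]
  res <- enumerate_formulas(123.4567, pos, tol_ppm = 0,
                            bounds = element_bounds(C = c(0, 5), H = c(0, 10),
                                                    N = c(0, 2), O = c(0, 5),
                                                    S = c(0, 1)))
  expect_identical(nrow(res), 0L)
})

test_that("formula enumeration equals brute-force grid search", {
  neg <- default_adducts()[2, ]
  b <- element_bounds(C = c(0, 10), H = c(0, 20), N = c(0, 2), O = c(0, 10),
                      S = c(0, 1))
  for (mz in c(GLUCOSE_MASS - 1.007276466, 150.0, 249.1234)) {
    for (tol in c(2, 5, 20)) {
      res <- enumerate_formulas(mz, neg, tol_ppm = tol, bounds = b)
      ref <- brute_force_formulas(mz, -1.007276466, tol, b)
      got <- res[order(res$C, res$H, res$N, res$O, res$S),
                 c("C", "H", "N", "O", "S")]
      rownames(got) <- NULL; rownames(ref) <- NULL
      expect_equal(got, ref, ignore_attr = TRUE)
    }
  }
})
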