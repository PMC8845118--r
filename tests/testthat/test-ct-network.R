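test_that("the study-scale prediction table yields the published arithmetic", {
  pred <- paper_scale_predictions(seed = 2)
  net <- build_ct_network(pred)
  s <- network_summary(net)
  expect_equal(unname(s["n_compounds"]), 60)
  expect_equal(unname(s["n_targets"]), 338)
  expect_equal(unname(s["n_nodes"]), 398)
  expect_equal(unname(s["n_edges"]), 985)
})

test_that("network construction deduplicates pairs and handles empties", {
  pred <- data.frame(compound_id = c("c1", "c1"), target_id = c("t1", "t1"),
                     stringsAsFactors = FALSE)
  expect_identical(nrow(build_ct_network(pred)$edges), 1L)
  empty <- build_ct_network(NULL)
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(length(empty$compound_nodes), 0L)
})

test_that("degree tables count incident edges with the handshake identity", {
  pred <- data.frame(
    compound_id = c("c1", "c1", "c1", "c1", "c1", "c2"),
    target_id = c("t1", "t2", "t3", "t4", "t5", "t1"),
    stringsAsFactors = FALSE)
  net <- build_ct_network(pred)
  dc <- degree_table(net, "compound")
  dt <- degree_table(net, "target")
  expect_identical(dc$degree[dc$id == "c1"], 5L)
  expect_identical(dc$degree[dc$id == "c2"], 1L)
  expect_identical(sum(dc$degree), nrow(net$edges))
  expect_identical(sum(dt$degree), nrow(net$edges))

  # handshake on random networks
  set.seed(41)
  for (i in 1:10) {
    p <- data.frame(compound_id = sample(paste0("c", 1:8), 30, TRUE),
                    target_id = sample(paste0("t", 1:12), 30, TRUE),
                    stringsAsFactors = FALSE)
    n <- build_ct_network(p)
    expect_identical(sum(degree_table(n, "compound")$degree), nrow(n$edges))
    expect_identical(sum(degree_table(n, "target")$degree), nrow(n$edges))
  }
})

test_that("core-constituent filter reproduces the published 19-survivor list", {
  core <- xdt_core_degrees()
  fillers <- data.frame(
    id = sprintf("FL%02d", 1:41),
    degree = rep(c(8L, 7L), times = c(31, 10)),
    part = "compound", stringsAsFactors = FALSE)
  tab <- rbind(data.frame(id = core$compound_id, degree = core$degree,
                          part = "compound", stringsAsFactors = FALSE),
               fillers)
  surv <- filter_core_constituents(tab, 17)
  expect_identical(nrow(surv), 19L)
  expect_identical(surv$degree[1], 75L)
  expect_identical(surv$id[1], "BB5")
  # boundary entry with degree exactly 17 is retained
  expect_true("RG2" %in% surv$id)
  expect_identical(min(surv$degree), 17L)
  # threshold above the maximum empties the list
  expect_identical(nrow(filter_core_constituents(tab, 76)), 0L)
})

test_that("survivors at a higher threshold are a subset of lower-threshold survivors", {
  pred <- paper_scale_predictions(seed = 3)
  deg <- degree_table(build_ct_network(pred), "compound")
  prev <- NULL
  for (th in c(5, 10, 17, 30, 50)) {
    cur <- filter_core_constituents(deg, th)$id
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the tripartite network adds exactly one edge per mapped target", {
  pred <- paper_scale_predictions(seed = 4)
  net <- build_ct_network(pred)
  cats <- paper_scale_category_map(seed = 4)
  tri <- build_ctd_network(net, cats)
  s <- network_summary(tri)
  expect_equal(unname(s["n_edges"]), 1323) # 985 + 338
  expect_identical(nrow(tri$tc_edges), 338L)

  # empty category map adds nothing
  tri0 <- build_ctd_network(net, NULL)
  expect_equal(unname(network_summary(tri0)["n_edges"]), 985)

  # unknown target is a referential error
  bad <- data.frame(target_id = "nonexistent", category = "inflammation")
  expect_error(build_ctd_network(net, bad), "unknown targets")

  # multi-category rows rejected unless opted in
  dup <- data.frame(target_id = c("TGT001", "TGT001"),
                    category = c("inflammation", "coagulation"))
  expect_error(build_ctd_network(net, dup), "multi")
  tri2 <- build_ctd_network(net, dup, multi = TRUE)
  expect_identical(nrow(tri2$tc_edges), 2L)
})

test_that("edge additivity holds on random tripartite networks", {
  set.seed(43)
  for (i in 1:10) {
    p <- data.frame(compound_id = sample(paste0("c", 1:6), 25, TRUE),
                    target_id = sample(paste0("t", 1:10), 25, TRUE),
                    stringsAsFactors = FALSE)
    net <- build_ct_network(p)
    mapped <- sample(net$target_nodes, sample(seq_along(net$target_nodes), 1))
    cats <- data.frame(target_id = mapped,
                       category = sample(c("a", "b", "c"), length(mapped), TRUE),
                       stringsAsFactors = FALSE)
    tri <- build_ctd_network(net, cats)
    expect_identical(nrow(net$edges) + nrow(tri$tc_edges),
                     as.integer(network_summary(tri)["n_edges"]))
  }
})

test_that("category counts realize the published per-pathology totals", {
  pred <- paper_scale_predictions(seed = 5)
  net <- build_ct_network(pred)
  tri <- build_ctd_network(net, paper_scale_category_map(seed = 5))
  cc <- category_counts(tri)
  expect_identical(sort(cc$n_targets, decreasing = TRUE),
                   c(111L, 79L, 46L, 41L, 27L, 18L, 9L, 7L))
  expect_identical(sum(cc$n_targets), 338L)

  # degenerate maps
  tri0 <- build_ctd_network(net, NULL)
  expect_identical(nrow(category_counts(tri0)), 0L)
  one_each <- data.frame(target_id = net$target_nodes[1:3],
                         category = c("x", "y", "z"), stringsAsFactors = FALSE)
  cc2 <- category_counts(build_ctd_network(net, one_each))
  expect_true(all(cc2$n_targets == 1L))
})

test_that("exports round-trip through SIF, TSV and GraphML", {
  pred <- data.frame(compound_id = c("c1", "c2", "c2"),
                     target_id = c("t1", "t1", "t2"), stringsAsFactors = FALSE)
  net <- build_ct_network(pred)
  cats <- data.frame(target_id = c("t1", "t2"),
                     category = c("inflammation", "coagulation"),
                     stringsAsFactors = FALSE)
  tri <- build_ctd_network(net, cats)
  want <- network_edge_key <- function(el) {
    sort(paste(el$source, el$interaction, el$target))
  }
  for (fmt in c("SIF", "TSV", "GraphML")) {
    f <- withr::local_tempfile(fileext = paste0(".", tolower(fmt)))
    export_network(tri, f, fmt)
    back <- import_network(f, fmt)
    expect_identical(nrow(back), 5L) # 3 ct + 2 tc
    ref <- rbind(data.frame(source = net$edges$compound_id, interaction = "ct",
                            target = net$edges$target_id),
                 data.frame(source = cats$target_id, interaction = "tc",
                            target = cats$category))
    expect_identical(want(back), want(ref))
  }
  # single-edge SIF line format
  f <- withr::local_tempfile()
  export_network(build_ct_network(pred[1, ]), f, "SIF")
  expect_identical(readLines(f), "c1\tct\tt1")
  expect_error(export_network(net, tempfile(), "XML"), "unknown")
})

test_that("a large TSV export has one row per edge", {
  net <- build_ct_network(paper_scale_predictions(seed = 6))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "TSV")
  expect_identical(length(readLines(f)), 986L) # header + 985 edges
})
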