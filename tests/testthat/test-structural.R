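PROTON <- 1.007276
SODIUM <- 22.989218

test_that("co-eluting pairs are linked as isotopologues and adducts", {
  # +1 isotopologue of a 585.2707 ion: Delta = 1.003355 (13C - 12C)
  f <- fm_tab(mz = c(585.2707, 585.2707 + 1.003355), rt = c(140.0, 140.3),
              assay = "HILIC+")
  e <- within_assay_links(f, ppm_tol = 5, rt_tol = 2)
  expect_equal(nrow(e), 1L)
  expect_equal(e$edge_type, "isotopologue")
  expect_match(e$rule, "k=1")
  expect_lt(e$ppm_error, 0.01)

  # [M+H]+ / [M+Na]+ pair of a 584.2634 Da neutral (bilirubin-like)
  M <- 584.2634
  f2 <- fm_tab(mz = c(M + PROTON, M + SODIUM), rt = c(140.0, 140.1),
               assay = "HILIC+")
  e2 <- within_assay_links(f2, ppm_tol = 5, rt_tol = 2)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$edge_type, "adduct")
  expect_equal(e2$rule, "[M+H]+/[M+Na]+")
  expect_lt(e2$ppm_error, 0.01)

  # the retention-time gate blocks the same masses when they do not co-elute
  f3 <- fm_tab(mz = c(M + PROTON, M + SODIUM), rt = c(140, 200),
               assay = "HILIC+")
  expect_equal(nrow(within_assay_links(f3, ppm_tol = 5, rt_tol = 2)), 0L)

  expect_equal(nrow(within_assay_links(f[0, ])), 0L)
})

test_that("cross-assay links require neutral-mass agreement but not RT", {
  M <- 584.2634
  f <- rbind(fm_tab(M + PROTON, 140.0, "HILIC+", ids = "h1"),
             fm_tab(M + SODIUM, 383.2, "LRPC+", ids = "l1"),
             fm_tab(M - PROTON, 52.9, "LRPC-", polarity = "negative",
                    ids = "n1"))
  e <- cross_assay_links(f, ppm_tol = 5)
  expect_equal(nrow(e), 3L)                     # all pairs share the neutral
  expect_true(all(e$edge_type == "cross_assay"))
  expect_true(all(e$ppm_error < 0.01))
  hp <- e[e$from == "h1" & e$to == "l1", ]
  expect_equal(hp$rule, "[M+H]+/[M+Na]+")

  # never emits an edge inside one assay
  f2 <- rbind(fm_tab(M + PROTON, 140, "HILIC+", ids = "a"),
              fm_tab(M + SODIUM, 140, "HILIC+", ids = "b"),
              fm_tab(M + PROTON, 300, "LRPC+", ids = "c"))
  e2 <- cross_assay_links(f2, ppm_tol = 5)
  expect_false(any(e2$from == "a" & e2$to == "b"))

  expect_error(cross_assay_links(fm_tab(100, 1, "A")), "two assays")
})

test_that("edge sets are symmetric in input order and monotone in tolerance", {
  set.seed(60)
  M <- c(300.1234, 451.2, 702.4)
  f <- rbind(fm_tab(c(M[1] + PROTON, M[1] + PROTON + 1.003355, M[1] + SODIUM),
                    c(100, 100.2, 100.4), "A+", ids = c("a1", "a2", "a3")),
             fm_tab(M[1] + PROTON, 210, "B+", ids = "b1"),
             fm_tab(c(M[2] + PROTON, M[3] + PROTON), c(50, 80), "B+",
                    ids = c("b2", "b3")))
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), e$edge_type))
  net1 <- search_features(f)
  perm <- f[sample(nrow(f)), ]
  net2 <- search_features(perm)
  expect_identical(key(net1$edges), key(net2$edges))

  e3 <- search_features(f, ppm_tol = 3)$edges
  e10 <- search_features(f, ppm_tol = 10)$edges
  expect_true(all(key(e3) %in% key(e10)))

  # stored ppm errors recompute from node m/z values
  for (i in seq_len(nrow(net1$edges))) {
    ed <- net1$edges[i, ]
    mzs <- f$mz[match(c(ed$from, ed$to), f$feature_id)]
    if (ed$edge_type == "isotopologue") {
      k <- as.numeric(sub(".*k=", "", ed$rule))
      err <- abs(abs(diff(mzs)) - k * 1.003355) / min(mzs) * 1e6
      expect_equal(ed$ppm_error, err, tolerance = 1e-9)
    }
  }
})

test_that("connected components form structural groups with summaries", {
  # chain a-b (isotopologue) + b-c (adduct) -> one group of three
  edges <- rbind(
    data.frame(from = "a", to = "b", edge_type = "isotopologue",
               rule = "13C isotopologue k=1", ppm_error = 0.1, rt_diff = 0.2,
               alternatives = ""),
    data.frame(from = "b", to = "c", edge_type = "adduct",
               rule = "[M+H]+/[M+Na]+", ppm_error = 0.5, rt_diff = 0.1,
               alternatives = ""))
  feats <- fm_tab(c(300, 301, 322), c(10, 10, 10), "A+",
                  ids = c("a", "b", "c"))
  feats <- rbind(feats, fm_tab(500, 99, "A+", ids = "lonely"))
  net <- build_structural_groups(edges, feats,
                                 cluster_labels = c(a = 1L, b = 1L, c = 1L,
                                                    lonely = 2L))
  expect_equal(nrow(net$groups), 1L)
  expect_equal(net$groups$n_features, 3L)
  expect_setequal(net$singletons, "lonely")
  expect_true(net$groups$within_one_cluster)
  expect_equal(net$cluster_agreement, 1)

  empty <- build_structural_groups(NULL, feats)
  expect_null(empty$groups)
  expect_length(empty$singletons, 4L)
})

test_that("a planted multi-assay ion series is recovered as one group", {
  M <- 584.2634
  f <- rbind(
    fm_tab(c(M + PROTON, M + PROTON + 1.003355, M + SODIUM),
           c(140, 140.2, 139.9), "HILIC+", ids = c("h1", "h2", "h3")),
    fm_tab(M + PROTON, 383, "LRPC+", ids = "l1"),
    fm_tab(M - PROTON, 52, "LRPC-", polarity = "negative", ids = "n1"),
    fm_tab(431.1, 222, "HILIC+", ids = "noise"))
  net <- search_features(f)
  expect_equal(nrow(net$groups), 1L)
  expect_equal(net$groups$n_features, 5L)
  expect_equal(net$groups$n_assays, 3L)
  expect_setequal(net$singletons, "noise")
})

test_that("ROI annotation is direct within tolerance and propagates to groups", {
  M <- 584.2634
  f <- rbind(fm_tab(c(M + PROTON, M + PROTON + 1.003355), c(140, 140.2),
                    "HILIC+", ids = c("h1", "h2")),
             fm_tab(800.4, 300, "HILIC+", ids = "far"))
  net <- search_features(f)
  roi <- data.frame(compound_name = "bilirubin", ref_mz = M + PROTON,
                    ref_rt = 140.0, assay = "HILIC+")
  net <- annotate_network(net, roi, ppm_tol = 5, rt_tol = 2)
  ann <- net$annotations
  expect_equal(ann$match[ann$feature_id == "h1"], "direct")
  # the isotopologue partner inherits the compound indirectly
  expect_equal(ann$match[ann$feature_id == "h2"], "indirect")
  expect_equal(unique(ann$compound_name), "bilirubin")
  expect_false("far" %in% ann$feature_id)
  expect_false(any(ann$conflict))

  # a feature 10 ppm away stays unannotated at 5 ppm
  f10 <- fm_tab((M + PROTON) * (1 + 10e-6), 140, "HILIC+", ids = "off")
  net10 <- annotate_network(build_structural_groups(NULL, f10), roi,
                            ppm_tol = 5, rt_tol = 2)
  expect_equal(nrow(net10$annotations), 0L)
})

test_that("networks export to GraphML plus flat node and edge tables", {
  M <- 584.2634
  f <- rbind(fm_tab(c(M + PROTON, M + SODIUM), c(140, 140.1), "HILIC+",
                    ids = c("h1", "h3")),
             fm_tab(M + PROTON, 383, "LRPC+", ids = "l1"))
  net <- search_features(f)
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  e <- read.csv(paths["edges"])
  expect_true(all(c("source", "target", "edge_type", "rule", "ppm_error")
                  %in% names(e)))
  n <- read.csv(paths["nodes"])
  expect_setequal(n$feature_id, f$feature_id)
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::gorder(g), 3L)
})
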