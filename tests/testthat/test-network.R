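test_that("pairwise matrices are symmetric with unit diagonal and guard smoothing", {
  cfg <- tiny_config(seed = 20)
  views <- build_analysis_views(generate_cohort(cfg))
  pm <- pairwise_matrix(views$unsmoothed, "patient")

  expect_equal(pm$r, t(pm$r))
  expect_equal(pm$p, t(pm$p))
  expect_equal(unname(diag(pm$r)), rep(1, length(pm$variables)))
  expect_equal(unname(diag(pm$p)), rep(0, length(pm$variables)))
  expect_equal(length(pm$variables), cfg$n_analytes + 1)
  expect_equal(pm$variables[1], "fatigue")
  expect_true(all(pm$n[-1, -1] == cfg$n_patients * cfg$n_days))

  expect_error(pairwise_matrix(views$smoothed, "patient"), "unsmoothed")
})

test_that("nest cytokines correlate more with each other than with independents", {
  cfg <- tiny_config(seed = 21)   # nest = cyto01..cyto06
  views <- build_analysis_views(generate_cohort(cfg))
  pm <- pairwise_matrix(views$unsmoothed, "patient")
  nest <- paste0("cyto", sprintf("%02d", 1:6))
  indep <- paste0("cyto", sprintf("%02d", 7:11))
  within <- pm$r[nest, nest][upper.tri(matrix(0, 6, 6))]
  between <- pm$r[nest, indep]
  expect_gt(mean(within), mean(between) + 0.05)
})

test_that("BH threshold equals the brute-force rule on the worked p-list", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  res <- bh_threshold(p, q = 0.05)
  oracle <- bh_oracle(p, 0.05)
  expect_equal(res$threshold, 0.008)
  expect_equal(res$threshold, oracle$threshold)
  expect_identical(res$rejected, oracle$rejected)
  expect_equal(res$n_rejected, 2)
})

test_that("BH agrees with brute force on random families and handles edge cases", {
  set.seed(30)
  for (i in 1:20) {
    p <- runif(50)^2
    q <- sample(c(0.01, 0.05, 0.1), 1)
    res <- bh_threshold(p, q)
    oracle <- bh_oracle(p, q)
    expect_identical(res$rejected, oracle$rejected)
    expect_equal(res$threshold, oracle$threshold)
  }
  expect_equal(bh_threshold(rep(0.5, 10), 0.01)$n_rejected, 0)
  expect_true(is.na(bh_threshold(rep(0.5, 10), 0.01)$threshold))
  expect_equal(bh_threshold(rep(0, 5), 0.01)$n_rejected, 5)
  expect_error(bh_threshold(c(0.1), 1.5), "q must")
  expect_error(bh_threshold(c(-0.1, 0.5), 0.05), "p-values")
})

test_that("BH rejection set is monotone non-decreasing in q", {
  set.seed(31)
  p <- runif(100)^1.5
  qs <- c(0.005, 0.01, 0.05, 0.1, 0.2)
  sets <- lapply(qs, function(q) which(bh_threshold(p, q)$rejected))
  for (i in seq_len(length(qs) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("networks are built from the rejected pairs only", {
  # Tiny hand-made pairwise object: 3 variables, one clearly significant pair.
  r <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.05, 0.1, 0.05, 1), 3, 3,
              dimnames = list(c("fatigue", "leptin", "cytoA"),
                              c("fatigue", "leptin", "cytoA")))
  p <- matrix(c(0, 1e-6, 0.8, 1e-6, 0, 0.9, 0.8, 0.9, 0), 3, 3,
              dimnames = dimnames(r))
  pm <- structure(list(r = r, p = p, n = matrix(25, 3, 3),
                       variables = rownames(r), group = "patient"),
                  class = "pairwise_matrix")
  net <- build_network(pm, q = 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$node1, net$edges$node2)),
               c("fatigue", "leptin"))
  expect_true(net$fatigue_leptin_edge)
  expect_equal(net$leptin_degree, 1)
  expect_setequal(net$highlighted, c("fatigue", "leptin"))

  # Nothing rejected -> edgeless graph with all nodes retained.
  p_null <- p; p_null[upper.tri(p_null)] <- 0.5; p_null[lower.tri(p_null)] <- 0.5
  pm_null <- pm; pm_null$p <- p_null
  net0 <- build_network(pm_null, q = 0.05)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(igraph::vcount(net0$graph), 3)
  expect_true(is.na(net0$threshold))
})

test_that("edge p-values never exceed the realized threshold", {
  cfg <- tiny_config(seed = 22)
  views <- build_analysis_views(generate_cohort(cfg))
  net <- build_network(pairwise_matrix(views$unsmoothed, "patient"), q = 0.01)
  expect_gt(nrow(net$edges), 0)   # planted nest guarantees discoveries
  expect_true(all(net$edges$p <= net$threshold))
  expect_lte(nrow(net$edges),
             length(net$nodes) * (length(net$nodes) - 1) / 2)
})

test_that("network edges are invariant to per-subject affine rescaling of analytes", {
  cfg <- tiny_config(seed = 23)
  cohort <- generate_cohort(cfg)
  rescaled <- cohort
  for (sid in unique(cohort$subject_id)) {
    idx <- rescaled$subject_id == sid
    rescaled$leptin[idx] <- rescaled$leptin[idx] * 3.7 + 11
  }
  net_a <- build_network(
    pairwise_matrix(build_analysis_views(cohort)$unsmoothed, "patient"))
  net_b <- build_network(
    pairwise_matrix(build_analysis_views(rescaled)$unsmoothed, "patient"))
  expect_equal(net_a$edges, net_b$edges)
})

test_that("layout is deterministic, framed, and symmetric for simple graphs", {
  r <- diag(2); dimnames(r) <- list(c("a", "b"), c("a", "b"))
  p <- matrix(c(0, 1e-9, 1e-9, 0), 2, 2, dimnames = dimnames(r))
  pm <- structure(list(r = r, p = p, n = matrix(25, 2, 2),
                       variables = c("a", "b"), group = "patient"),
                  class = "pairwise_matrix")
  net2 <- build_network(pm, q = 0.05)
  xy <- fr_layout(net2, seed = 3)
  expect_equal(unname(sqrt(sum(xy[1, ]^2))), unname(sqrt(sum(xy[2, ]^2))),
               tolerance = 1e-8)                     # equidistant from center
  expect_identical(xy, fr_layout(net2, seed = 3))    # seeded determinism
  expect_false(identical(xy, fr_layout(net2, seed = 4)))

  single <- net2
  single$nodes <- "a"
  expect_equal(unname(fr_layout(single)), matrix(0, 1, 2))  # frame center

  cfg <- tiny_config(seed = 24)
  views <- build_analysis_views(generate_cohort(cfg))
  net <- build_network(pairwise_matrix(views$unsmoothed, "patient"))
  coords <- fr_layout(net, seed = 9)
  expect_true(all(abs(coords) <= 1 + 1e-9))
  expect_equal(rownames(coords), net$nodes)
})

test_that("network files round-trip through GraphML and the edge list", {
  cfg <- tiny_config(seed = 25)
  views <- build_analysis_views(generate_cohort(cfg))
  net <- build_network(pairwise_matrix(views$unsmoothed, "patient"))
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  write_network_graphml(net, gml)
  write_edge_list(net, tsv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(net$edges))
  edges <- read.delim(tsv)
  expect_equal(nrow(edges), nrow(net$edges))
  expect_named(edges, c("node1", "node2", "r", "p"))
  unlink(c(gml, tsv))
})
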