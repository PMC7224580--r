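# Connectivity geometry: Delta selection, spanning forest, refinement,
# and the K-fold visibility ratio.

test_that("closed-form Delta reproduces the reference values", {
  expect_equal(round(choose_delta(4.67e8, v_h = 256, coverage = 0.99), 2),
               0.17)
  # direct arithmetic at the smallest admissible sample
  expect_equal(choose_delta(2, v_h = 256, coverage = 0.99),
               (24 * 256 * 0.99 / pi^4)^(1 / 8))
  expect_equal(round(choose_delta(2), 3), 1.677)
  # strictly decreasing in the effective sample size
  ns <- c(10, 1e3, 1e5, 1e7, 1e9)
  expect_true(all(diff(vapply(ns, choose_delta, numeric(1))) < 0))
  expect_error(choose_delta(1), "at least 2")
})

test_that("effective sample size scales with the bistable increase", {
  expect_equal(effective_sample_size(3208681, 27508, 4e6) / 4.67e8, 1,
               tolerance = 0.002)
  expect_equal(effective_sample_size(500, 500, 1e4), 1e4)
  expect_equal(effective_sample_size(1000, 500, 1e4),
               2 * effective_sample_size(500, 500, 1e4))
  expect_error(effective_sample_size(10, 0, 100), "positive")
})

test_that("spanning forest matches hand-checkable configurations", {
  pts <- cbind(c(0, 0.1, 0.2), 0)
  g <- build_spanning_forest(pts, 0.15)
  expect_identical(g$n_components, 1L)
  expect_identical(nrow(g$edges), 2L)

  far <- rbind(pts, cbind(c(10, 10.1), 0))
  g2 <- build_spanning_forest(far, 0.15)
  expect_identical(g2$n_components, 2L)

  single <- build_spanning_forest(matrix(0, 1, 8), 0.15)
  cs <- summarize_components(single)
  expect_identical(cs$n_components, 1L)
  expect_identical(cs$c1, 1L)
  expect_identical(cs$n_singletons, 1L)

  empty <- summarize_components(
    build_spanning_forest(matrix(0, 0, 8), 0.15))
  expect_identical(empty$n_points, 0L)
})

test_that("forest components equal brute-force transitive closure", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- c(120, 200, 350, 500)[seed]
    d <- c(2L, 8L, 3L, 8L)[seed]
    pts <- matrix(stats::runif(n * d, -1, 1), ncol = d)
    delta <- c(0.4, 0.9, 0.3, 1.0)[seed]
    g <- build_spanning_forest(pts, delta)
    expect_true(same_partition(g$labels, brute_components(pts, delta)))
    # a forest is acyclic: edges = vertices - components
    expect_identical(nrow(g$edges), as.integer(n - g$n_components))
  }
})

test_that("two dense blobs give two large components", {
  set.seed(2)
  a <- matrix(stats::runif(400, -0.1, 0.1), ncol = 2)
  b <- a + 5
  g <- build_spanning_forest(rbind(a, b), 0.15)
  cs <- summarize_components(g)
  expect_identical(cs$n_components, 2L)
  expect_identical(cs$c1, 200L)
  expect_identical(cs$c2, 200L)
})

test_that("refinement bridges a dumbbell region through the neck", {
  ind <- dumbbell_indicator(width = 0.2)
  set.seed(14)
  cand <- matrix(stats::runif(8000 * 3, -1, 1), ncol = 3)
  pts <- cand[ind(cand), , drop = FALSE]
  # drop bridge points so the initial graph is disconnected
  lobes <- pts[abs(pts[, 1]) >= 0.5, , drop = FALSE]
  g <- build_spanning_forest(lobes, 0.3)
  expect_gt(g$n_components, 1L)
  ref <- refine_components(g, ind,
                           connectivity_config(delta = 0.3), seed = 3)
  expect_identical(ref$graph$n_components, 1L)
  expect_gt(nrow(ref$newfound), 0L)
  expect_true(all(ind(ref$newfound)))
  # an already-connected graph comes back unchanged
  done <- refine_components(ref$graph, ind,
                            connectivity_config(delta = 0.3))
  expect_identical(nrow(done$history), 0L)
  expect_identical(done$graph$labels, ref$graph$labels)
})

test_that("visibility is exactly 1 on a convex region", {
  set.seed(6)
  pts <- matrix(stats::runif(400, -1, 1), ncol = 4)
  est <- estimate_visibility(pts, box_indicator(rep(-1, 4), rep(1, 4)),
                             M = 200, K = 10, seed = 7)
  expect_equal(est$ratio, 1)
})

test_that("K-fold visibility overestimates and approaches brute force", {
  ind <- annulus_indicator(0.6, 1)
  set.seed(10)
  cand <- matrix(stats::runif(8000, -1, 1), ncol = 2)
  pts <- cand[ind(cand), , drop = FALSE]
  v10 <- estimate_visibility(pts, ind, M = 400, K = 10, seed = 11)$ratio
  v50 <- estimate_visibility(pts, ind, M = 400, K = 50, seed = 11)$ratio
  vfine <- estimate_visibility(pts, ind, M = 400, K = 400, seed = 11)$ratio
  expect_gte(v10, v50)
  expect_gte(v50, vfine)
  expect_lt(abs(v50 - vfine), 0.02)
  expect_lt(abs(v10 - vfine), 0.05)
})

test_that("visibility CI covers the known ratio of two disjoint boxes", {
  # equal-volume convex boxes far apart: segments within a box are fully
  # inside, cross-box segments leave the region; the population K-fold
  # ratio equals the within-box pair fraction, computable exactly
  ind <- function(points) {
    points <- rbind(points)
    x <- points[, 1]
    (x >= -1 & x <= -0.6) | (x >= 0.6 & x <= 1)
  }
  set.seed(20)
  n <- 400
  x <- c(stats::runif(n / 2, -1, -0.6), stats::runif(n / 2, 0.6, 1))
  pts <- cbind(x, matrix(stats::runif(n, -1, 1), ncol = 1))
  truth <- {   # exact population fraction of ordered same-box pairs
    side <- x >= 0
    n1 <- sum(side); n2 <- n - n1
    (n1 * (n1 - 1) + n2 * (n2 - 1)) / (n * (n - 1))
  }
  hits <- 0L
  for (t in 1:200) {
    est <- estimate_visibility(pts, ind, M = 150, K = 10,
                               seed = 3000 + t)
    if (est$ci_low <= truth && truth <= est$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("segment interior points exclude the endpoints", {
  a <- c(0, 0); b <- c(1, 2)
  s <- ptmgeo:::segment_interior(a, b, 10)
  expect_identical(dim(s), c(10L, 2L))
  expect_equal(s[1, ], (b - a) / 11)
  expect_equal(s[10, ], 10 * (b - a) / 11)
})
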