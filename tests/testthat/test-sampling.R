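# ILR sampling, the volume estimator and its confidence intervals, and
# the VEGAS adaptive sampler.

test_that("ILR sampling is uniform in log10, bounded and reproducible", {
  pts <- ilr_sample(1e4, sampling_box(1, 8), seed = 9)
  expect_identical(dim(pts), c(10000L, 8L))
  expect_true(all(pts >= -1 & pts <= 1))
  for (j in c(1L, 5L, 8L))
    expect_gt(stats::ks.test(pts[, j], "punif", -1, 1)$p.value, 0.01)
  expect_identical(pts, ilr_sample(1e4, sampling_box(1, 8), seed = 9))
  expect_false(identical(pts[1, ], ilr_sample(1e4, sampling_box(1, 8),
                                              seed = 10)[1, ]))
  one <- ilr_sample(1, sampling_box(2, 6), seed = 1)
  expect_identical(dim(one), c(1L, 6L))
  expect_true(all(one >= -2 & one <= 2))
})

test_that("sampling does not disturb the caller's random state", {
  set.seed(123)
  before <- .Random.seed
  invisible(ilr_sample(10, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("volume estimator arithmetic matches the closed form", {
  pts <- matrix(0, 100, 8)
  s <- fake_labelled(pts, rep(c(TRUE, FALSE), each = 50))
  est <- estimate_volume(s, 10)
  expect_equal(est$v_hat, 0.5)
  hw <- 1.96 * sqrt(0.25 * 100 / 99) / 10
  expect_equal(est$ci_high - est$v_hat, hw, tolerance = 1e-3)
  expect_equal(est$v_hat - est$ci_low, hw, tolerance = 1e-3)

  all_bi <- estimate_volume(fake_labelled(pts, rep(TRUE, 100)), 10)
  expect_equal(all_bi$v_hat, 1)
  expect_equal(all_bi$ci_low, 1)
  expect_equal(all_bi$ci_high, 1)

  none <- estimate_volume(fake_labelled(pts, rep(FALSE, 100)), 10)
  expect_equal(none$v_hat, 0)
  expect_true(none$degenerate_ci)
  expect_equal(none$ci_high, 3 / 100)   # rule of three
})

test_that("volume CI has nominal coverage on an analytic region", {
  # sub-box of known log-volume fraction, indicator evaluated exactly
  ind <- box_indicator(rep(-1, 8), c(0, 0, 0, rep(1, 5)))
  f <- 1 / 8
  hits <- 0L
  for (t in 1:200) {
    pts <- ilr_sample(1000, sampling_box(1, 8), seed = 5000 + t)
    est <- estimate_volume(fake_labelled(pts, ind(pts)), 10)
    if (est$ci_low <= f && f <= est$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
})

test_that("nongeneric labels are excluded from the volume estimate", {
  pts <- matrix(0, 10, 8)
  s <- fake_labelled(pts, rep(c(TRUE, FALSE), each = 5))
  s$labels[1:2, 1] <- "NONGENERIC"
  est <- estimate_volume(s, 10)
  expect_equal(est$n, 8L)
  expect_equal(est$v_hat, 3 / 8)
})

test_that("labelling across an empty sigma grid yields empty labels", {
  pts <- ilr_sample(3, seed = 1)
  lab <- label_sample(pts, numeric(0))
  expect_identical(dim(lab$labels), c(3L, 0L))
})

test_that("sigma grid presets are increasing and correctly restricted", {
  expect_identical(length(sigma_grid("MAIN15")), 15L)
  expect_identical(sigma_grid("VEGAS12"), sigma_grid("MAIN15")[4:15])
  expect_identical(sigma_grid("CONNECT14"), sigma_grid("MAIN15")[2:15])
  expect_identical(length(sigma_grid("FINE6")), 6L)
  expect_error(sigma_grid(c(2, 1)), "increasing")
})

test_that("VEGAS smoothing floors empty bins at one", {
  f <- ptmgeo:::vegas_smoothed_freq(c(-0.95, -0.94, -0.93),
                                    seq(-1, 1, length.out = 51), 1000)
  expect_identical(length(f), 50L)
  expect_true(all(f >= 1L))
  expect_identical(sum(f > 1L), 1L)   # only the occupied bin rises
})

test_that("VEGAS grids stay a partition of [-1, 1] and draws stay inside", {
  g <- vegas_grid(dimension = 3, M = 50, K = 1000)
  set.seed(8)
  blob <- matrix(stats::runif(600, -0.2, 0.1), ncol = 3)
  st <- vegas_step(blob, g, 500, seed = 2)
  expect_identical(dim(st$points), c(500L, 3L))
  expect_true(all(st$points >= -1 & st$points <= 1))
  for (j in 1:3) {
    e <- st$grid$edges[, j]
    expect_equal(e[1], -1)
    expect_equal(e[51], 1)
    expect_true(all(diff(e) > 0))
    expect_equal(sum(diff(e)), 2)
  }
  # uniform input density leaves the bins equal up to smoothing rounding
  unif <- matrix(stats::runif(3e4, -1, 1), ncol = 3)
  stu <- vegas_step(unif, vegas_grid(3), 100, seed = 3)
  expect_lt(max(abs(diff(stu$grid$edges[, 1]) - 2 / 50)), 0.01)
})

test_that("VEGAS concentrates sampling on a dense synthetic region", {
  # region: corner box occupying 1/4 of each of 3 axes (volume 1/64)
  ind <- box_indicator(rep(-1, 3), rep(-0.5, 3))
  set.seed(21)
  seeds <- matrix(stats::runif(4000 * 3, -1, 1), ncol = 3)
  seed_bi <- seeds[ind(seeds), , drop = FALSE]
  expect_gt(nrow(seed_bi), 0)
  run <- vegas_run(seed_bi, iterations = 2, n_per_iter = 2000,
                   indicator = ind, seed = 22,
                   reference_fraction = nrow(seed_bi) / 4000)
  expect_gt(run$enrichment, 10)
  expect_true(all(run$bistable >= -1 & run$bistable <= 1))
})

test_that("a VEGAS run with no iterations returns the seed set", {
  seed_set <- matrix(stats::runif(80, -1, 1), ncol = 8)
  run <- vegas_run(seed_set, iterations = 0, n_per_iter = 100,
                   indicator = function(p) rep(TRUE, nrow(rbind(p))))
  expect_identical(run$bistable, seed_set)
  expect_identical(run$n_drawn, 0L)
  expect_error(vegas_run(seed_set[0, , drop = FALSE], 1, 10,
                         function(p) TRUE),
               "ILR")
})

test_that("volume grows with the box exponent at saturating sigma", {
  n <- 5e4
  v1 <- {
    lab <- label_sample(ilr_sample(n, sampling_box(1, 8), seed = 61), 500)
    estimate_volume(lab, 500)
  }
  v2 <- {
    lab <- label_sample(ilr_sample(n, sampling_box(2, 8), seed = 62), 500)
    estimate_volume(lab, 500)
  }
  expect_lt(v1$v_hat, v2$v_hat)
})
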