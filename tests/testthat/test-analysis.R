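# Cross-sigma analyses: threshold scan, blinking, rebinding tradeoff.

test_that("no bistability is detectable at sigma = 1 but plenty at 10", {
  scan <- threshold_scan(sampling_box(1, 8), n = 5000,
                         sigma_values = c(1, 10), seed = 41)
  expect_identical(scan$counts$n_bistable[1], 0L)
  expect_gt(scan$counts$n_bistable[2], 0L)
  expect_equal(scan$sigma_first_hit, 10)
})

test_that("blinking is detected at the fourth reference point only", {
  fx <- fixture_points()
  lab <- label_sample(log10(fx$theta), fx$sigma)
  bs <- blinking_summary(lab, delta = 0.15)
  tab <- bs$table
  # the blinking reference point is bistable at 4, monostable at 5 and 7
  expect_identical(tab$bp[tab$sigma == 4], 1L)
  # the point that stays bistable from 5 onward never blinks
  expect_identical(tab$bp[tab$sigma == 7], 0L)
  # the transiently bistable point blinks at sigma = 5
  expect_identical(tab$bp[tab$sigma == 5], 1L)
  expect_true(all(tab$bpsc <= tab$bp))
  expect_true(all(tab$bpnl <= tab$bp))
  expect_true(all(tab$bpam <= tab$bp))
})

test_that("monotone profiles produce no blinking", {
  pts <- matrix(stats::runif(40, -1, 1), ncol = 8)
  lab <- fake_labelled(pts, rep(FALSE, 15), sigma = c(2, 5, 10))
  lab$labels <- cbind(`2` = rep("MONOSTABLE", 5),
                      `5` = c("BISTABLE", "MONOSTABLE", "BISTABLE",
                              "MONOSTABLE", "MONOSTABLE"),
                      `10` = c("BISTABLE", "BISTABLE", "BISTABLE",
                               "MONOSTABLE", "BISTABLE"))
  bs <- blinking_summary(lab)
  expect_true(all(bs$table$bp == 0L))
})

test_that("a nongeneric entry disqualifies a point from blinking counts", {
  pts <- matrix(stats::runif(16, -1, 1), ncol = 8)
  lab <- fake_labelled(pts, c(TRUE, TRUE), sigma = c(5, 10))
  lab$labels <- cbind(`5` = c("BISTABLE", "BISTABLE"),
                      `10` = c("MONOSTABLE", "NONGENERIC"))
  bs <- blinking_summary(lab)
  expect_identical(bs$table$bp, 1L)
  expect_identical(bs$n_excluded, 1L)
})

test_that("the tradeoff bound is the bistable maximum of eps2*phi0", {
  pts <- matrix(log10(0.5), 6, 8)
  pts[, 5] <- log10(0.1)   # eps2
  pts[, 6] <- log10(0.1)   # phi0
  s <- fake_labelled(pts, rep(TRUE, 6))
  tb <- tradeoff_bound(s, 10)
  expect_equal(tb$k_hat, 0.01)
  expect_identical(tb$count_above(0.005), 6L)
  expect_identical(tb$count_above(0.02), 0L)
  # no bistable point can violate its own maximum
  expect_identical(tb$count_above(tb$k_hat), 0L)

  strong <- fake_labelled(pts[, 1:6], rep(TRUE, 6), mode = "strong")
  expect_error(tradeoff_bound(strong, 10), "strong")
})
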