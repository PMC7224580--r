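# The steady-state polynomial system: construction, the two assembly
# routes, and recovery of full concentrations from a solution.

test_that("printed coefficient examples hold", {
  p1 <- ptm_params(1, 1, 1, 1, 1, 1, 1, 1)
  for (sg in c(1, 10, 500)) {
    sys <- build_system(p1, ptm_totals(sg))
    expect_identical(drop(eval_phi(sys, 0, 0)), c(phi1 = 0, phi2 = 0))
    # at zeta = 1: Phi1(1,1) = -sigma(a e0 + e1 + b e2), Phi2 analogous
    expect_equal(unname(eval_phi(sys, 1, 1)[, "phi1"]), -sg * 3)
    expect_equal(unname(eval_phi(sys, 1, 1)[, "phi2"]), -sg * 3)
  }
  # generic parameters, zeta = 1
  th <- c(2.1, 0.4, 1.3, 0.7, 3.2, 0.2, 1.9, 0.8)
  sys <- build_system(as_ptm_params(th), ptm_totals(7))
  expect_equal(unname(eval_phi(sys, 1, 1)[, "phi1"]),
               -7 * (th[1] * th[3] + th[4] + th[2] * th[5]))
  expect_equal(unname(eval_phi(sys, 1, 1)[, "phi2"]),
               -7 * (th[1] * th[6] + th[7] + th[2] * th[8]))
})

test_that("strong irreversibility zeroes every rebinding term exactly", {
  th <- c(2, 0.5, 1.5, 0.8, 0, 0, 1.2, 3)
  sys <- build_system(as_ptm_params(th, mode = "strong"), ptm_totals(10))
  # all monomials carrying eps2 or phi0
  expect_identical(sys$phi1["u4", "v0"], 0)   # -b e2 z^2 u^4
  expect_identical(sys$phi1["u0", "v3"], 0)   # a f0 v^3
  expect_identical(sys$phi1["u1", "v3"], 0)   # -a f0 u v^3
  expect_identical(sys$phi2["u0", "v4"], 0)   # -a f0 v^4
  expect_identical(sys$phi2["u3", "v0"], 0)   # b e2 z^2 u^3
  expect_identical(sys$phi2["u3", "v1"], 0)   # -b e2 z^2 u^3 v
})

test_that("expanded and psi assembly routes agree coefficient-wise", {
  set.seed(11)
  for (i in 1:1000) {
    th <- 10^stats::runif(8, -1, 1)
    tot <- ptm_totals(sigma = 10^stats::runif(1, 0, 2.7),
                      lam = 10^stats::runif(1, 0, 2.7),
                      zeta = 10^stats::runif(1, -0.5, 0.5))
    a <- build_system(as_ptm_params(th), tot)
    b <- build_system_via_psi(as_ptm_params(th), tot)
    scale <- max(abs(a$phi1), abs(a$phi2))
    expect_lt(max(abs(a$phi1 - b$phi1), abs(a$phi2 - b$phi2)),
              1e-10 * scale)
  }
})

test_that("the two routes evaluate identically at random interior points", {
  th <- as_ptm_params(c(3.7, 0.2, 0.9, 1.4, 2.2, 0.3, 1.1, 0.6))
  tot <- ptm_totals(5, lam = 8, zeta = 1.7)
  a <- build_system(th, tot)
  b <- build_system_via_psi(th, tot)
  set.seed(5)
  u <- stats::runif(100); v <- stats::runif(100)
  ea <- eval_phi(a, u, v); eb <- eval_phi(b, u, v)
  expect_lt(max(abs(ea - eb)), 1e-10 * max(abs(ea)))
})

test_that("psi coefficient triples follow the non-dimensionalisation", {
  th <- c(2, 0.5, 1.5, 0.8, 0.4, 0.3, 1.2, 3)
  ps <- psi_coefficients(as_ptm_params(th), ptm_totals(10, zeta = 1))
  expect_equal(unname(ps["psi1", ]), c(th[1], 1, th[2]))
  expect_equal(unname(ps["psi2", ]), c(th[3] * th[1], th[4], th[5] * th[2]))
  expect_equal(unname(ps["psi3", ]), c(th[6] * th[1], th[7], th[8] * th[2]))
})

test_that("parameter validation rejects non-positive and bad strong inputs", {
  expect_error(ptm_params(0, 1, 1, 1, 1, 1, 1, 1), "positive")
  expect_error(ptm_params(1, 1, 1, 1, -1, 1, 1, 1), "non-negative")
  expect_error(ptm_params(1, 1, 1, 1, 1, 1, 1, 1, mode = "strong"),
               "strong")
  expect_error(ptm_totals(0), "positive")
  expect_silent(ptm_params(1, 1, 1, 1, 0, 0, 1, 1, mode = "strong"))
})

test_that("concentrations recovered from a solution satisfy conservation", {
  fx <- fixture_points()
  params <- as_ptm_params(fx$theta[1, ])
  tot <- ptm_totals(10)
  sys <- build_system(params, tot)
  sol <- solve_system(sys)
  pos <- sol$solutions[sol$solutions$positive_real, ]
  expect_equal(nrow(pos), 1L)
  u <- Re(pos$u[1]); v <- Re(pos$v[1])
  conc <- recover_concentrations(u, v, params, tot)
  expect_lt(conc$residual, 1e-8)
  # enzyme conservation: free enzyme cannot exceed the total
  expect_true(u > 0 && u <= 1)
  expect_true(v > 0 && v <= 1)
  # modform ratio identities
  expect_equal(conc$s0 / conc$s1, params$theta[["alpha"]] * v / u)
  expect_equal(conc$s2 / conc$s1, params$theta[["beta"]] * u / v)
  # a non-solution is rejected
  expect_error(recover_concentrations(u + 0.1, v, params, tot),
               "tolerance")
})

test_that("swapping the enzymes and the variables preserves the system", {
  # relabelling the enzymes (and reversing the modform order) maps
  # theta -> (b, a, f2, f1, f0, e2, e1, e0) and (u, v) -> (v, u); the two
  # polynomials swap exactly, so the solution set is carried over
  swap <- function(th) c(th[2], th[1], th[8], th[7], th[6],
                         th[5], th[4], th[3])
  set.seed(77)
  for (i in 1:25) {
    th <- 10^stats::runif(8, -1, 1)
    tot <- ptm_totals(10)
    a <- build_system(as_ptm_params(th), tot)
    b <- build_system(as_ptm_params(swap(th)), tot)
    expect_equal(unname(t(b$phi1)), unname(a$phi2))
    expect_equal(unname(t(b$phi2)), unname(a$phi1))
  }
  th <- 10^stats::runif(8, -1, 1)
  s1 <- solve_system(build_system(as_ptm_params(th), ptm_totals(10)))
  s2 <- solve_system(build_system(as_ptm_params(swap(th)),
                                  ptm_totals(10)))
  expect_equal(s1$n_positive_real, s2$n_positive_real)
  expect_lt(match_solutions(s1$solutions$u, s1$solutions$v,
                            s2$solutions$v, s2$solutions$u), 1e-6)
})
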