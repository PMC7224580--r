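# Exhaustive solution of the steady-state system: reference points,
# generic solution structure, classification and certification.

test_that("reference parameter points give the generic solution pattern", {
  fx <- fixture_points()
  tot <- ptm_totals(10)
  s1 <- solve_system(build_system(as_ptm_params(fx$theta[1, ]), tot))
  expect_identical(s1$origin_multiplicity, 6L)
  expect_identical(s1$n_finite_nonzero, 7L)
  expect_identical(s1$n_positive_real, 1L)
  expect_identical(s1$stationarity, "MONOSTABLE")

  s2 <- solve_system(build_system(as_ptm_params(fx$theta[2, ]), tot))
  expect_identical(s2$n_positive_real, 3L)
  expect_identical(s2$stationarity, "BISTABLE")

  s3 <- solve_system(build_system(as_ptm_params(fx$theta[3, ]),
                                  ptm_totals(7)))
  expect_identical(s3$n_positive_real, 1L)

  # strong variant of the first point: five finite nonzero solutions
  ths <- fx$theta[1, c(1:4, 7:8)]
  ss <- solve_system(build_system(as_ptm_params(ths, mode = "strong"),
                                  tot))
  expect_identical(ss$origin_multiplicity, 6L)
  expect_identical(ss$n_finite_nonzero, 5L)
})

test_that("the full reference stationarity matrix is reproduced", {
  fx <- fixture_points()
  lab <- label_sample(log10(fx$theta), fx$sigma)
  expect_identical(unname(lab$labels), unname(fx$expected))
  expect_true(all(lab$nongeneric == 0L))
})

test_that("generic counts and parity hold on random draws", {
  th <- random_theta(200, seed = 31)
  res <- ptmgeo:::label_batch(th, 10)
  ok <- res[, "status"] < 2L
  expect_gte(mean(ok), 0.99)
  # Bezout bookkeeping: 6 at the origin + 7 finite nonzero (weak)
  expect_true(all(res[ok, "origin_mult"] == 6L))
  expect_true(all(res[ok, "n_proper"] == 7L))
  expect_true(all(res[ok, "origin_mult"] + res[ok, "n_proper"] == 13L))
  expect_true(all(res[ok, "n_pos_real"] %in% c(1L, 3L)))

  ths <- random_theta(100, seed = 32, mode = "strong")
  ress <- ptmgeo:::label_batch(ths, 10, mode = "strong")
  oks <- ress[, "status"] < 2L
  expect_gte(mean(oks), 0.99)
  expect_true(all(ress[oks, "origin_mult"] + ress[oks, "n_proper"] == 11L))
  expect_true(all(ress[oks, "n_pos_real"] %in% c(1L, 3L)))
})

test_that("origin multiplicity is 6 generically and warns when crowded", {
  th <- random_theta(50, seed = 33)
  for (i in 1:50) {
    sys <- build_system(as_ptm_params(th[i, ]), ptm_totals(10))
    expect_identical(origin_multiplicity(sys), 6L)
  }
})

test_that("opposite elimination orders find the same solution set", {
  th <- random_theta(200, seed = 34)
  tot <- ptm_totals(10)
  for (i in 1:200) {
    sys <- build_system(as_ptm_params(th[i, ]), tot)
    a <- solve_system(sys)
    # transposing both grids swaps the roles of u and v, so the first
    # eliminated variable changes
    swapped <- sys
    swapped$phi1 <- t(sys$phi1)
    swapped$phi2 <- t(sys$phi2)
    b <- solve_system(swapped)
    expect_identical(a$n_finite_nonzero, b$n_finite_nonzero)
    expect_lt(match_solutions(a$solutions$u, a$solutions$v,
                              b$solutions$v, b$solutions$u), 1e-8)
  }
})

test_that("returned solutions satisfy the residual bound", {
  th <- random_theta(50, seed = 35)
  for (i in 1:50) {
    sys <- build_system(as_ptm_params(th[i, ]), ptm_totals(10))
    sol <- solve_system(sys)$solutions
    # moderate-size solutions; at larger |u|, |v| the attainable absolute
    # residual scales with the monomial magnitudes, not the coefficients
    small <- Mod(sol$u) <= 2 & Mod(sol$v) <= 2
    if (!any(small)) next
    resid <- eval_phi(sys, sol$u[small], sol$v[small])
    expect_lt(max(Mod(resid)), 1e-10 * max(abs(sys$phi1), abs(sys$phi2)))
  }
})

test_that("coordinate classification follows the printed case analysis", {
  expect_identical(classify_coordinate(complex(real = 0.5,
                                               imaginary = 1e-30)),
                   "nonzero_real")
  expect_identical(classify_coordinate(complex(real = 0.5,
                                               imaginary = 1e-15)),
                   "ambiguous")
  expect_identical(classify_coordinate(1e9 + 0i), "infinite")
  expect_identical(classify_coordinate(1e-12 + 1e-12i), "small")
  expect_identical(classify_coordinate(0.5 + 0.5i), "nonzero_nonreal")
  # the small case precedes the ambiguous one
  expect_identical(classify_coordinate(1e-12 + 1e-20i), "small")
  # vectorised
  expect_identical(classify_coordinate(c(1 + 0i, 1e9 + 0i)),
                   c("nonzero_real", "infinite"))
})

test_that("Newton contraction certifies solutions and rejects the rest", {
  fx <- fixture_points()
  sys <- build_system(as_ptm_params(fx$theta[1, ]), ptm_totals(10))
  sol <- solve_system(sys)
  expect_true(all(sol$solutions$certified))
  # the origin is singular (multiplicity 6)
  expect_false(certify_newton(0 + 0i, 0 + 0i, sys))
  # a perturbed non-solution
  s1 <- sol$solutions[1, ]
  expect_false(certify_newton(s1$u + 0.1, s1$v, sys))
})

test_that("a degenerate system raises an error instead of fake counts", {
  sys <- build_system(ptm_params(1, 1, 1, 1, 1, 1, 1, 1), ptm_totals(10))
  sys$phi1[] <- 0
  sys$phi2[] <- 0
  expect_error(solve_system(sys), "degenerate")
})
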