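# Solution finding, classification and certification.

solver_opts <- function(thresholds, mode) {
  expected <- switch(mode, weak = 7L, strong = 5L, none = -1L)
  list(t_zmin = thresholds$t_zmin, t_zmax = thresholds$t_zmax,
       t_inf = thresholds$t_inf, newton_tol = thresholds$newton_tol,
       expected_nf = expected, max_retry = 2L)
}

stationarity_from_counts <- function(status, n_pos) {
  ifelse(status >= 2L, "NONGENERIC",
         ifelse(n_pos == 3L, "BISTABLE",
                ifelse(n_pos == 1L, "MONOSTABLE", "NONGENERIC")))
}

#' Find all finite solutions of a steady-state system
#'
#' Computes every finite complex solution of \eqn{\{\Phi_1 = 0, \Phi_2 =
#' 0\}} by Sylvester-resultant elimination (determinant interpolated from
#' evaluations at scaled roots of unity), univariate Aberth root finding,
#' back-substitution and Newton polish, then classifies each coordinate,
#' certifies solutions by Newton contraction, and labels the parameter
#' point.  Generically the origin has multiplicity 6 and there are seven
#' (weak mode) or five (strong mode) further finite solutions, of which
#' one or three are positive real: monostability or bistability.  Points
#' failing the generic pattern after the retry ladder (swapped elimination
#' order, changed evaluation radius, tightened ambiguity band) are flagged
#' `NONGENERIC`, never silently dropped.
#'
#' @param system A `ptm_system` from [build_system()].
#' @param thresholds A [classifier_thresholds()] object.
#' @return An object of class `ptm_solutions`: data frame `solutions`
#'   (complex `u`, `v`, relative residual, coordinate classes, `positive_real`,
#'   `certified`), plus `origin_multiplicity`, `n_finite_nonzero`,
#'   `n_positive_real`, `stationarity` (`MONOSTABLE`/`BISTABLE`/`NONGENERIC`)
#'   and solver diagnostics.
#' @export
#' @examples
#' th1 <- fixture_points()$theta[1, ]
#' sys <- build_system(as_ptm_params(th1), ptm_totals(10))
#' sol <- solve_system(sys)
#' sol$n_finite_nonzero   # 7
#' sol$stationarity       # "MONOSTABLE"
solve_system <- function(system, thresholds = classifier_thresholds()) {
  stopifnot(inherits(system, "ptm_system"))
  det <- cpp_solve_detail(as.numeric(system$phi1), as.numeric(system$phi2),
                          solver_opts(thresholds, system$params$mode))
  if (det$status == 3L)
    stop("degenerate system: identically zero resultant", call. = FALSE)
  cls_u <- classify_coordinate(det$u, thresholds)
  cls_v <- classify_coordinate(det$v, thresholds)
  nz <- c("nonzero_real", "nonzero_nonreal")
  proper <- cls_u %in% nz & cls_v %in% nz
  pos <- cls_u == "nonzero_real" & cls_v == "nonzero_real" &
    Re(det$u) > thresholds$t_zmax & Re(det$v) > thresholds$t_zmax
  certified <- vapply(seq_along(det$u), function(i)
    certify_newton(det$u[i], det$v[i], system, thresholds), logical(1))
  sols <- data.frame(u = det$u, v = det$v,
                     residual = det$rel_residual,
                     class_u = cls_u, class_v = cls_v,
                     proper = proper, positive_real = pos,
                     certified = certified)
  stationarity <- stationarity_from_counts(det$status, sum(pos))
  structure(list(solutions = sols,
                 origin_multiplicity = det$origin_mult,
                 n_finite_nonzero = sum(proper),
                 n_positive_real = sum(pos),
                 stationarity = stationarity,
                 status = det$status,
                 n_attempts = det$n_attempts,
                 eliminated = det$eliminated,
                 system = system,
                 thresholds = thresholds),
            class = "ptm_solutions")
}

#' @export
print.ptm_solutions <- function(x, ...) {
  cat(sprintf(
    "Solution set: origin multiplicity %d, %d finite nonzero, %d positive real -> %s\n",
    x$origin_multiplicity, x$n_finite_nonzero, x$n_positive_real,
    x$stationarity))
  invisible(x)
}

#' @export
summary.ptm_solutions <- function(object, ...) {
  print(object)
  df <- object$solutions
  df$u <- signif(df$u, 6)
  df$v <- signif(df$v, 6)
  df$residual <- signif(df$residual, 3)
  print(df)
  invisible(object)
}

#' Local intersection multiplicity of the origin
#'
#' The origin \eqn{u = v = 0} is always a solution; its local intersection
#' multiplicity is computed as the multiplicity of the \eqn{u = 0} root of
#' the resultant eliminating \eqn{v}, after confirming that no other
#' solution has \eqn{u} within `t_zmax` of zero.  Generically 6.
#'
#' @inheritParams solve_system
#' @return Integer multiplicity.
#' @export
origin_multiplicity <- function(system,
                                thresholds = classifier_thresholds()) {
  stopifnot(inherits(system, "ptm_system"))
  det <- cpp_solve_detail(as.numeric(system$phi1), as.numeric(system$phi2),
                          solver_opts(thresholds, system$params$mode))
  if (det$status == 3L)
    stop("degenerate system: identically zero resultant", call. = FALSE)
  if (any(Mod(det$u) <= thresholds$t_zmax & Mod(det$v) > thresholds$t_zmax))
    warning("another solution has u near 0; multiplicity read off the ",
            "resultant may overcount")
  det$origin_mult
}

#' Classify a solution coordinate
#'
#' Case analysis on \eqn{x^* = a^* + i b^*} against the thresholds
#' \eqn{T_{zmin} \le T_{zmax} \ll 1 \ll T_\infty}, evaluated in order:
#' *small* if \eqn{|a^*|, |b^*| < T_{zmax}}; *ambiguous* if
#' \eqn{T_{zmin} < |b^*| < T_{zmax}}; *infinite* if \eqn{|a^*| > T_\infty}
#' or \eqn{|b^*| > T_\infty}; *nonzero real* if
#' \eqn{T_{zmax} < |a^*| < T_\infty} and \eqn{|b^*| < T_{zmin}};
#' otherwise *nonzero non-real*.
#'
#' @param x Complex vector.
#' @param thresholds A [classifier_thresholds()] object.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_coordinate(complex(real = 0.5, imaginary = 1e-30))  # nonzero_real
#' classify_coordinate(complex(real = 0.5, imaginary = 1e-15))  # ambiguous
classify_coordinate <- function(x, thresholds = classifier_thresholds()) {
  a <- abs(Re(x)); b <- abs(Im(x))
  out <- rep("nonzero_nonreal", length(x))
  out[a > thresholds$t_zmax & a < thresholds$t_inf &
        b < thresholds$t_zmin] <- "nonzero_real"
  out[a > thresholds$t_inf | b > thresholds$t_inf] <- "infinite"
  out[b > thresholds$t_zmin & b < thresholds$t_zmax] <- "ambiguous"
  out[a < thresholds$t_zmax & b < thresholds$t_zmax] <- "small"
  out
}

#' Certify a solution by Newton contraction
#'
#' A numerical solution is certified when Newton's method on the full
#' system, started at the solution, contracts at least quadratically over
#' three successive iterations and the Jacobian at the endpoint is
#' non-singular.  Singular solutions (the origin, multiplicity 6) and
#' non-solutions fail.  This replaces exact alpha-theory certification
#' with a practical contraction test.
#'
#' @param u,v Complex scalars: the approximate solution.
#' @param system The `ptm_system` it should solve.
#' @param thresholds A [classifier_thresholds()] object.
#' @return Logical.
#' @export
certify_newton <- function(u, v, system,
                           thresholds = classifier_thresholds()) {
  g1 <- system$phi1; g2 <- system$phi2
  powers <- function(x) rbind(x^(0:4))
  dpowers <- function(x) rbind(c(0 + 0i, (1:4) * x^(0:3)))
  jac_step <- function(u, v) {
    pu <- powers(u); pv <- powers(v)
    du <- dpowers(u); dv <- dpowers(v)
    f1 <- sum((pu %*% g1) * pv);  f2 <- sum((pu %*% g2) * pv)
    f1u <- sum((du %*% g1) * pv); f2u <- sum((du %*% g2) * pv)
    f1v <- sum((pu %*% g1) * dv); f2v <- sum((pu %*% g2) * dv)
    det <- f1u * f2v - f1v * f2u
    scale <- sum(abs(g1)) * max(1, abs(u), abs(v))^8
    if (abs(det) < 1e-14 * max(1, scale)) return(NULL)  # singular Jacobian
    c((f1 * f2v - f2 * f1v) / det, (f2 * f1u - f1 * f2u) / det)
  }
  u <- as.complex(u); v <- as.complex(v)
  steps <- numeric(3)
  for (k in 1:3) {
    d <- jac_step(u, v)
    if (is.null(d)) return(FALSE)
    steps[k] <- sqrt(abs(d[1])^2 + abs(d[2])^2)
    u <- u - d[1]; v <- v - d[2]
    if (!all(is.finite(c(Re(u), Im(u), Re(v), Im(v))))) return(FALSE)
  }
  size <- 1 + abs(u) + abs(v)
  # quadratic contraction: each step's square dominates the next, with a
  # conditioning allowance; immediate convergence to rounding also passes
  tiny <- 1e-13 * size
  contracts <- all(steps[-1] <= pmax(1e3 * steps[-3]^2, tiny))
  contracts && steps[3] < 1e-6 * size
}

# Batch labelling over many parameter points (internal work-horse).
# theta: n x 8 natural-scale matrix. Returns integer matrix from C++.
label_batch <- function(theta, sigma, lam = sigma, zeta = 1,
                        mode = "weak",
                        thresholds = classifier_thresholds()) {
  cc <- phi_coefficient_rows(theta, sigma, lam, zeta)
  cpp_label_batch(cc$c1, cc$c2, solver_opts(thresholds, mode))
}
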