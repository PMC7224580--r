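# Steady-state polynomial system construction.
#
# The reduced steady state of the two-site system is the common zero set of
# two bivariate polynomials Phi1(u, v), Phi2(u, v) of total degree 4 in the
# free-enzyme fractions u = [E]/E_tot, v = [F]/F_tot.  Coefficient grids are
# stored as 5x5 matrices c[i+1, j+1] multiplying u^i v^j.

# Vectorised coefficient assembly: theta columns are alpha, beta, eps0, eps1,
# eps2, phi0, phi1, phi2 on the natural (not log) scale.  Returns n x 25
# matrices in column-major (i + 5*j + 1) grid order.  This is the single
# implementation behind both the scalar constructor and the batch labeller.
phi_coefficient_rows <- function(theta, sigma, lam, zeta) {
  theta <- rbind(theta) # tolerate a bare vector
  a  <- theta[, 1]; b  <- theta[, 2]
  e0 <- theta[, 3]; e1 <- theta[, 4]; e2 <- theta[, 5]
  f0 <- theta[, 6]; f1 <- theta[, 7]; f2 <- theta[, 8]
  z <- zeta
  n <- nrow(theta)
  c1 <- matrix(0, n, 25L)
  c2 <- matrix(0, n, 25L)
  idx <- function(i, j) i + 5L * j + 1L
  # Phi1
  c1[, idx(0, 2)] <- a
  c1[, idx(1, 1)] <- z
  c1[, idx(2, 0)] <- b * z^2
  c1[, idx(1, 2)] <- a * e0 * (1 - sigma) - a + f1 * z
  c1[, idx(2, 1)] <- e1 * z * (1 - sigma) - z + b * f2 * z^2
  c1[, idx(3, 0)] <- b * e2 * z^2 * (1 - sigma) - b * z^2
  c1[, idx(0, 3)] <- a * f0
  c1[, idx(2, 2)] <- -(a * e0 + f1 * z)
  c1[, idx(3, 1)] <- -(e1 * z + b * f2 * z^2)
  c1[, idx(4, 0)] <- -b * e2 * z^2
  c1[, idx(1, 3)] <- -a * f0
  # Phi2
  c2[, idx(0, 2)] <- a
  c2[, idx(1, 1)] <- z
  c2[, idx(2, 0)] <- b * z^2
  c2[, idx(0, 3)] <- a * f0 * (1 - lam) - a
  c2[, idx(1, 2)] <- f1 * z * (1 - lam) - z + a * e0
  c2[, idx(2, 1)] <- b * f2 * z^2 * (1 - lam) - b * z^2 + e1 * z
  c2[, idx(3, 0)] <- b * e2 * z^2
  c2[, idx(1, 3)] <- -(a * e0 + f1 * z)
  c2[, idx(2, 2)] <- -(e1 * z + b * f2 * z^2)
  c2[, idx(3, 1)] <- -b * e2 * z^2
  c2[, idx(0, 4)] <- -a * f0
  list(c1 = c1, c2 = c2)
}

new_ptm_system <- function(phi1, phi2, params, totals) {
  dn <- list(paste0("u", 0:4), paste0("v", 0:4))
  dimnames(phi1) <- dn
  dimnames(phi2) <- dn
  structure(list(phi1 = phi1, phi2 = phi2,
                 params = params, totals = totals),
            class = "ptm_system")
}

#' Build the steady-state polynomial system
#'
#' Assembles the pair of bivariate quartics \eqn{\Phi_1(u,v)},
#' \eqn{\Phi_2(u,v)} whose common zeros are the steady states of the
#' two-site modification cycle, directly from the expanded coefficient
#' table.  The origin \eqn{u = v = 0} is always a solution, so both
#' constant terms are zero.
#'
#' @param params A [ptm_params()] object.
#' @param totals A [ptm_totals()] object.
#' @return An object of class `ptm_system` holding two 5x5 coefficient
#'   grids (`phi1`, `phi2`; entry `[i+1, j+1]` multiplies `u^i v^j`) and the
#'   provenance `params`/`totals`.
#' @seealso [build_system_via_psi()] for the algebraically independent
#'   assembly route, [solve_system()].
#' @export
#' @examples
#' sys <- build_system(ptm_params(1, 1, 1, 1, 1, 1, 1, 1), ptm_totals(10))
#' eval_phi(sys, 0, 0)   # both zero: the origin is always a solution
build_system <- function(params, totals) {
  stopifnot(inherits(params, "ptm_params"), inherits(totals, "ptm_totals"))
  cc <- phi_coefficient_rows(params$theta, totals$sigma, totals$lam,
                             totals$zeta)
  new_ptm_system(matrix(cc$c1[1L, ], 5L, 5L), matrix(cc$c2[1L, ], 5L, 5L),
                 params, totals)
}

#' The rational functions psi1, psi2, psi3
#'
#' Coefficient triples over the monomial basis \eqn{\{v/u,\ 1,\ u/v\}}:
#' \eqn{\psi_1 = (\alpha/\zeta)(v/u) + 1 + \beta\zeta(u/v)},
#' \eqn{\psi_2 = (\epsilon_0\alpha/\zeta)(v/u) + \epsilon_1 +
#' \epsilon_2\beta\zeta(u/v)}, and
#' \eqn{\psi_3 = (\phi_0\alpha/\zeta)(v/u) + \phi_1 + \phi_2\beta\zeta(u/v)}.
#' These arise from eliminating the modform and complex concentrations in
#' favour of the free-enzyme fractions.
#'
#' @inheritParams build_system
#' @return A 3x3 numeric matrix, rows `psi1..psi3`, columns
#'   `v_over_u`, `one`, `u_over_v`.
#' @export
psi_coefficients <- function(params, totals) {
  stopifnot(inherits(params, "ptm_params"), inherits(totals, "ptm_totals"))
  th <- params$theta; z <- totals$zeta
  m <- rbind(
    psi1 = c(th[["alpha"]] / z, 1, th[["beta"]] * z),
    psi2 = c(th[["eps0"]] * th[["alpha"]] / z, th[["eps1"]],
             th[["eps2"]] * th[["beta"]] * z),
    psi3 = c(th[["phi0"]] * th[["alpha"]] / z, th[["phi1"]],
             th[["phi2"]] * th[["beta"]] * z))
  colnames(m) <- c("v_over_u", "one", "u_over_v")
  m
}

# shift a 5x5 grid by (du, dv) powers, i.e. multiply by u^du v^dv,
# erroring if that would overflow degree 4
grid_shift <- function(g, du, dv) {
  out <- matrix(0, 5L, 5L)
  out[(1L + du):5L, (1L + dv):5L] <- g[1L:(5L - du), 1L:(5L - dv)]
  if (any(g[if (du > 0) (5L - du + 1L):5L else 0, ] != 0) ||
      any(g[, if (dv > 0) (5L - dv + 1L):5L else 0] != 0))
    stop("degree overflow in grid shift")
  out
}

#' Build the system through the psi route
#'
#' Assembles \eqn{\Phi_k} as
#' \eqn{\Phi_1 = \zeta u v\,[(1-u)(\psi_1 + u\psi_2 + v\psi_3) -
#' \sigma u \psi_2]} and
#' \eqn{\Phi_2 = \zeta u v\,[(1-v)(\psi_1 + u\psi_2 + v\psi_3) -
#' \lambda v \psi_3]} by polynomial arithmetic on the
#' [psi_coefficients()].  Algebraically identical to [build_system()];
#' serves as an independent assembly route that guards against
#' transcription errors in the 24-term expanded form.
#'
#' @inheritParams build_system
#' @return A `ptm_system`, coefficient-wise equal to [build_system()]'s to
#'   machine precision.
#' @export
build_system_via_psi <- function(params, totals) {
  psi <- psi_coefficients(params, totals)
  z <- totals$zeta
  # B_k = zeta*u*v*psi_k is the polynomial  a_k v^2 + m_k zeta u v + c_k zeta^2 u^2
  B <- lapply(1:3, function(k) {
    g <- matrix(0, 5L, 5L)
    g[1L, 3L] <- psi[k, "v_over_u"] * z   # v^2
    g[2L, 2L] <- psi[k, "one"] * z        # u v
    g[3L, 1L] <- psi[k, "u_over_v"] * z   # u^2
    g
  })
  S <- B[[1L]] + grid_shift(B[[2L]], 1L, 0L) + grid_shift(B[[3L]], 0L, 1L)
  phi1 <- S - grid_shift(S, 1L, 0L) -
    totals$sigma * grid_shift(B[[2L]], 1L, 0L)
  phi2 <- S - grid_shift(S, 0L, 1L) -
    totals$lam * grid_shift(B[[3L]], 0L, 1L)
  new_ptm_system(phi1, phi2, params, totals)
}

#' Evaluate the system at points (u, v)
#'
#' @param system A `ptm_system`.
#' @param u,v Numeric or complex vectors (recycled to a common length).
#' @return A two-column matrix with columns `phi1`, `phi2`.
#' @export
eval_phi <- function(system, u, v) {
  stopifnot(inherits(system, "ptm_system"))
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  pow_u <- outer(u, 0:4, `^`)
  pow_v <- outer(v, 0:4, `^`)
  cbind(phi1 = rowSums((pow_u %*% system$phi1) * pow_v),
        phi2 = rowSums((pow_u %*% system$phi2) * pow_v))
}

#' @export
print.ptm_system <- function(x, digits = 4, ...) {
  cat("Steady-state polynomial system Phi1 = Phi2 = 0\n")
  print(x$params)
  print(x$totals)
  cat("Phi1 coefficients (rows u^0..u^4, cols v^0..v^4):\n")
  print(signif(x$phi1, digits))
  cat("Phi2 coefficients:\n")
  print(signif(x$phi2, digits))
  invisible(x)
}

#' Recover steady-state concentrations from a solution
#'
#' Given a positive real solution `(u, v)` of the system, recovers the
#' modform fractions \eqn{s_0, s_1, s_2} (in units of \eqn{S_{tot}}) and the
#' total enzyme-substrate complex concentrations per enzyme.  Substrate
#' conservation \eqn{s_0 + s_1 + s_2 + c_E + c_F = 1} holds by construction
#' of the algebra; enzyme conservation requires \eqn{0 < u, v \le 1}.
#'
#' @param u,v Positive reals solving the system.
#' @inheritParams build_system
#' @param tol Relative tolerance for accepting `(u, v)` as a solution.
#' @return An object of class `ptm_concentrations`: list with `u`, `v`,
#'   `s0`, `s1`, `s2`, `complex_totals` (named `E`, `F`), and the
#'   conservation `residual`.
#' @export
recover_concentrations <- function(u, v, params, totals, tol = 1e-8) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == 1L, length(v) == 1L)
  if (u <= 0 || v <= 0)
    stop("concentration recovery needs a positive real solution",
         call. = FALSE)
  psi <- psi_coefficients(params, totals)
  basis <- c(v / u, 1, u / v)
  ps <- unname(drop(psi %*% basis))      # psi1, psi2, psi3 at (u, v)
  denom <- ps[1L] + u * ps[2L] + v * ps[3L]
  s1 <- 1 / denom
  # consistency: u = 1/(1 + sigma*s1*psi2), v = 1/(1 + lam*s1*psi3)
  ures <- abs(u - 1 / (1 + totals$sigma * s1 * ps[2L]))
  vres <- abs(v - 1 / (1 + totals$lam * s1 * ps[3L]))
  if (ures > tol * max(1, u) || vres > tol * max(1, v))
    stop("(u, v) does not satisfy the steady-state system within tolerance",
         call. = FALSE)
  s0 <- params$theta[["alpha"]] * v / (totals$zeta * u) * s1
  s2 <- params$theta[["beta"]] * totals$zeta * u / v * s1
  cE <- u * ps[2L] * s1
  cF <- v * ps[3L] * s1
  structure(list(u = u, v = v, s0 = s0, s1 = s1, s2 = s2,
                 complex_totals = c(E = cE, F = cF),
                 residual = abs(s0 + s1 + s2 + cE + cF - 1)),
            class = "ptm_concentrations")
}

#' @export
print.ptm_concentrations <- function(x, ...) {
  cat(sprintf("Steady state at u = %.6g, v = %.6g\n", x$u, x$v))
  cat(sprintf("  modforms  s0 = %.6g  s1 = %.6g  s2 = %.6g\n",
              x$s0, x$s1, x$s2))
  cat(sprintf("  complexes E = %.6g  F = %.6g  (units of S_tot)\n",
              x$complex_totals[["E"]], x$complex_totals[["F"]]))
  cat(sprintf("  conservation residual %.3g\n", x$residual))
  invisible(x)
}
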