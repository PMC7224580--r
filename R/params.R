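#' Non-dimensional parameters of the two-site PTM system
#'
#' A parameter point \eqn{\theta = (\alpha, \beta, \epsilon_0, \epsilon_1,
#' \epsilon_2, \phi_0, \phi_1, \phi_2)} describing one two-site, sequential,
#' distributive modification cycle.  \eqn{\alpha} and \eqn{\beta} are ratios
#' of total generalised catalytic efficiencies of the forward and reverse
#' enzymes; the \eqn{\epsilon}'s and \eqn{\phi}'s are reciprocal total
#' generalised Michaelis-Menten constants non-dimensionalised by the
#' corresponding enzyme total.  Under weak irreversibility all eight entries
#' are positive; strong irreversibility forbids product rebinding of the
#' intermediate modform, forcing \eqn{\epsilon_2 = \phi_0 = 0} exactly, and
#' the point lives in the 6-dimensional \eqn{\eta}-space
#' \eqn{(\alpha, \beta, \epsilon_0, \epsilon_1, \phi_1, \phi_2)}.
#'
#' @param alpha,beta Positive catalytic-efficiency ratios.
#' @param eps0,eps1,phi1,phi2 Positive binding parameters.
#' @param eps2,phi0 Non-negative product-rebinding parameters; must be 0 in
#'   strong mode.
#' @param mode `"weak"` or `"strong"` irreversibility.
#' @return An object of class `ptm_params`.
#' @seealso [as_ptm_params()] to build from a numeric vector in \eqn{\theta}
#'   (or strong-mode \eqn{\eta}) order, [build_system()].
#' @export
#' @examples
#' ptm_params(1, 1, 1, 1, 1, 1, 1, 1)
#' ptm_params(2, 0.5, 1, 1, 0, 0, 1, 1, mode = "strong")
ptm_params <- function(alpha, beta, eps0, eps1, eps2, phi0, phi1, phi2,
                       mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  th <- c(alpha = alpha, beta = beta, eps0 = eps0, eps1 = eps1,
          eps2 = eps2, phi0 = phi0, phi1 = phi1, phi2 = phi2)
  if (!is.numeric(th) || length(th) != 8L || any(!is.finite(th)))
    stop("all eight parameters must be finite numerics", call. = FALSE)
  strict <- th[c("alpha", "beta", "eps0", "eps1", "phi1", "phi2")]
  if (any(strict <= 0))
    stop("alpha, beta, eps0, eps1, phi1, phi2 must be strictly positive",
         call. = FALSE)
  if (th[["eps2"]] < 0 || th[["phi0"]] < 0)
    stop("eps2 and phi0 must be non-negative", call. = FALSE)
  if (mode == "strong" && (th[["eps2"]] != 0 || th[["phi0"]] != 0))
    stop("strong irreversibility requires eps2 = phi0 = 0 exactly",
         call. = FALSE)
  structure(list(theta = th, mode = mode), class = "ptm_params")
}

#' Coerce a numeric vector to `ptm_params`
#'
#' @param x Numeric vector of length 8 in \eqn{\theta}-order
#'   \eqn{(\alpha,\beta,\epsilon_0,\epsilon_1,\epsilon_2,\phi_0,\phi_1,\phi_2)},
#'   or of length 6 in strong-mode \eqn{\eta}-order
#'   \eqn{(\alpha,\beta,\epsilon_0,\epsilon_1,\phi_1,\phi_2)}.
#' @param mode `"weak"` or `"strong"`; a length-6 `x` implies `"strong"`.
#' @return A `ptm_params` object.
#' @export
as_ptm_params <- function(x, mode = if (length(x) == 6L) "strong" else "weak") {
  x <- as.numeric(x)
  if (length(x) == 6L) {
    if (mode != "strong")
      stop("a 6-parameter point is only meaningful in strong mode",
           call. = FALSE)
    x <- c(x[1:4], 0, 0, x[5:6])
  }
  if (length(x) != 8L)
    stop("expected 8 (weak) or 6 (strong) parameter values", call. = FALSE)
  ptm_params(x[1], x[2], x[3], x[4], x[5], x[6], x[7], x[8], mode = mode)
}

#' @export
print.ptm_params <- function(x, ...) {
  cat("Two-site PTM parameter point (", x$mode, " irreversibility)\n",
      sep = "")
  print(signif(x$theta, 7))
  invisible(x)
}

#' Conserved totals, non-dimensionalised
#'
#' \eqn{\sigma = S_{tot}/E_{tot}}, \eqn{\lambda = S_{tot}/F_{tot}},
#' \eqn{\zeta = E_{tot}/F_{tot}}.  The default configuration used throughout
#' the analyses sets \eqn{E_{tot} = F_{tot}}, i.e. \eqn{\zeta = 1} and
#' \eqn{\lambda = \sigma}, with \eqn{\sigma} the parameter that varies.
#'
#' @param sigma Substrate abundance relative to the forward enzyme; positive.
#' @param lam \eqn{\lambda}; defaults to `sigma`.
#' @param zeta \eqn{\zeta}; defaults to 1.
#' @return An object of class `ptm_totals`.
#' @export
ptm_totals <- function(sigma, lam = sigma, zeta = 1) {
  vals <- c(sigma = sigma, lam = lam, zeta = zeta)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("sigma, lam, zeta must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "ptm_totals")
}

#' @export
print.ptm_totals <- function(x, ...) {
  cat(sprintf("Conserved totals: sigma = %g, lambda = %g, zeta = %g\n",
              x$sigma, x$lam, x$zeta))
  invisible(x)
}

#' Logarithmic sampling box H_p
#'
#' The box \eqn{H_p = [0.1^p, 10^p]^d}: each parameter's log10 value lies in
#' \eqn{[-p, p]}.  `d = 8` for weak irreversibility, `d = 6` for strong.
#' The log-volume of the box is \eqn{(2p)^d}.
#'
#' @param p Positive box exponent (the analyses use p = 1, ..., 5).
#' @param dimension 8 or 6.
#' @return An object of class `sampling_box` with fields `p`, `dimension`,
#'   `log_volume`.
#' @export
#' @examples
#' sampling_box(1, 8)$log_volume  # 256
sampling_box <- function(p = 1, dimension = 8) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("p must be a positive scalar", call. = FALSE)
  dimension <- as.integer(dimension)
  if (!dimension %in% c(6L, 8L))
    stop("dimension must be 8 (weak) or 6 (strong)", call. = FALSE)
  structure(list(p = p, dimension = dimension,
                 log_volume = (2 * p)^dimension),
            class = "sampling_box")
}

#' @export
print.sampling_box <- function(x, ...) {
  cat(sprintf("Sampling box [0.1^%g, 10^%g]^%d (log-volume %g)\n",
              x$p, x$p, x$dimension, x$log_volume))
  invisible(x)
}

#' Solution-classification thresholds
#'
#' Thresholds for classifying a numerically computed solution coordinate
#' \eqn{x^* = a^* + i b^*} as small, ambiguous, infinite, nonzero real or
#' nonzero non-real, and the relative residual tolerance for Newton
#' refinement.  Defaults are the first-pass values used throughout:
#' \eqn{T_{zmin} = 10^{-25}}, \eqn{T_{zmax} = 10^{-10}},
#' \eqn{T_\infty = 10^8}.
#'
#' @param t_zmin,t_zmax Magnitude thresholds separating true zeros from
#'   ambiguous near-zeros; `0 < t_zmin <= t_zmax << 1`.
#' @param t_inf Magnitude beyond which a coordinate is treated as
#'   projectively infinite.
#' @param newton_tol Relative residual tolerance for refined solutions.
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(t_zmin = 1e-25, t_zmax = 1e-10,
                                  t_inf = 1e8, newton_tol = 1e-12) {
  t_zmin <- as.numeric(t_zmin); t_zmax <- as.numeric(t_zmax)
  t_inf <- as.numeric(t_inf); newton_tol <- as.numeric(newton_tol)
  if (!(t_zmin > 0 && t_zmin <= t_zmax && t_zmax < 1 && t_inf > 1))
    stop("need 0 < t_zmin <= t_zmax << 1 << t_inf", call. = FALSE)
  if (newton_tol <= 0) stop("newton_tol must be positive", call. = FALSE)
  structure(list(t_zmin = t_zmin, t_zmax = t_zmax, t_inf = t_inf,
                 newton_tol = newton_tol),
            class = "classifier_thresholds")
}
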