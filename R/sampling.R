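# ILR sampling, batch labelling and bistable-volume estimation.

#' Sigma grids
#'
#' Named presets of substrate-abundance values \eqn{\sigma = S_{tot}/E_{tot}}
#' used across the analyses:
#' `MAIN15` (the main 15-value grid from 1.0 to 500), `VEGAS12`
#' (the subset \eqn{\sigma \ge 2.5} used to seed adaptive sampling),
#' `CONNECT14` (\eqn{\sigma \ge 1.5}, connectivity analysis), `FINE6`
#' (six values between 1 and 1.25 bracketing the bistability threshold) and
#' `STRONG_EXTRA` (1000, 2000, 5000, strong irreversibility only).
#'
#' @param preset Preset name, or a numeric vector of sigma values.
#' @return A strictly increasing numeric vector of positive sigma values.
#' @export
#' @examples
#' sigma_grid("MAIN15")
#' sigma_grid(c(3, 4, 5, 7, 10))
sigma_grid <- function(preset = "MAIN15") {
  if (is.numeric(preset)) {
    s <- as.numeric(preset)
  } else {
    main15 <- c(1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 5.0, 7.0, 10, 15, 20,
                50, 100, 200, 500)
    s <- switch(match.arg(preset,
                          c("MAIN15", "VEGAS12", "CONNECT14", "FINE6",
                            "STRONG_EXTRA")),
                MAIN15 = main15,
                VEGAS12 = main15[main15 >= 2.5],
                CONNECT14 = main15[main15 >= 1.5],
                FINE6 = c(1.0078125, 1.015625, 1.03125, 1.0625, 1.125,
                          1.25),
                STRONG_EXTRA = c(1000, 2000, 5000))
  }
  if (length(s) && (any(s <= 0) || is.unsorted(s, strictly = TRUE)))
    stop("sigma values must be positive and strictly increasing",
         call. = FALSE)
  s
}

#' Independent Logarithmic Random sampling
#'
#' Draws `n` parameter points from the box \eqn{H_p = [0.1^p, 10^p]^d} by
#' sampling each coordinate's log10 value independently and uniformly from
#' \eqn{[-p, p]}.  Reproducible: the same seed yields the same table, and
#' the caller's random state is untouched.
#'
#' @param n Number of points.
#' @param box A [sampling_box()].
#' @param seed Integer seed.
#' @return An `n` x `d` matrix of log10 coordinates with attributes `box`
#'   and `seed`; columns named `theta1..theta8` (weak) or `eta1..eta6`
#'   (strong-mode boxes).
#' @export
ilr_sample <- function(n, box = sampling_box(1, 8), seed = 1) {
  stopifnot(inherits(box, "sampling_box"), n >= 1)
  d <- box$dimension
  pts <- with_seed(seed,
                   matrix(stats::runif(n * d, -box$p, box$p), nrow = n))
  colnames(pts) <- if (d == 8L) paste0("theta", 1:8) else paste0("eta", 1:6)
  attr(pts, "box") <- box
  attr(pts, "seed") <- seed
  pts
}

# expand log10 points to the natural-scale 8-column theta matrix
theta_natural <- function(points, mode) {
  th <- 10^unname(points)
  if (mode == "strong") {
    if (ncol(th) == 6L) th <- cbind(th[, 1:4, drop = FALSE], 0, 0,
                                    th[, 5:6, drop = FALSE])
    else { th[, 5] <- 0; th[, 6] <- 0 }
  }
  if (ncol(th) != 8L) stop("points must have 8 (weak) or 6 (strong) columns")
  th
}

#' Label a parameter sample across a sigma grid
#'
#' Runs the exhaustive solver at every (point, sigma) combination with
#' \eqn{\zeta} fixed and \eqn{\lambda = \sigma} unless overridden, and
#' records the stationarity of each.  Points failing the generic solution
#' pattern are flagged `NONGENERIC` (with a logged tally) and are excluded
#' from downstream estimates, never silently dropped.
#'
#' @param points Matrix of log10 coordinates (8 columns weak, 6 strong),
#'   e.g. from [ilr_sample()].
#' @param sigma Numeric vector of sigma values (see [sigma_grid()]).
#' @param mode `"weak"` or `"strong"`.
#' @param zeta \eqn{E_{tot}/F_{tot}}; default 1.
#' @param lam Optional explicit \eqn{\lambda} values (recycled over
#'   `sigma`); default `lam = sigma`.
#' @param thresholds A [classifier_thresholds()] object.
#' @return An object of class `labelled_sample`: the `points`, the `sigma`
#'   grid, a character `labels` matrix (`n` x `length(sigma)`) with entries
#'   `MONOSTABLE`/`BISTABLE`/`NONGENERIC`, and per-sigma `nongeneric` and
#'   `retried` tallies.
#' @export
label_sample <- function(points, sigma, mode = c("weak", "strong"),
                         zeta = 1, lam = NULL,
                         thresholds = classifier_thresholds()) {
  mode <- match.arg(mode)
  sigma <- as.numeric(sigma)
  points <- rbind(points)
  n <- nrow(points)
  th <- theta_natural(points, mode)
  labels <- matrix(character(0), n, 0)
  nongeneric <- integer(0)
  retried <- integer(0)
  for (k in seq_along(sigma)) {
    lk <- if (is.null(lam)) sigma[k] else rep_len(lam, length(sigma))[k]
    res <- label_batch(th, sigma[k], lk, zeta, mode, thresholds)
    lab <- stationarity_from_counts(res[, "status"], res[, "n_pos_real"])
    labels <- cbind(labels, lab)
    nongeneric <- c(nongeneric, sum(res[, "status"] >= 2L))
    retried <- c(retried, sum(res[, "status"] == 1L))
  }
  colnames(labels) <- as.character(sigma)
  structure(list(points = points, sigma = sigma, labels = labels,
                 mode = mode, zeta = zeta,
                 box = attr(points, "box"), seed = attr(points, "seed"),
                 nongeneric = stats::setNames(nongeneric,
                                              as.character(sigma)),
                 retried = stats::setNames(retried, as.character(sigma))),
            class = "labelled_sample")
}

#' @export
print.labelled_sample <- function(x, ...) {
  cat(sprintf("Labelled sample: %d points (%s mode) x %d sigma values\n",
              nrow(x$points), x$mode, length(x$sigma)))
  nb <- colSums(x$labels == "BISTABLE")
  tab <- data.frame(sigma = x$sigma, bistable = nb,
                    nongeneric = as.integer(x$nongeneric),
                    retried = as.integer(x$retried))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo estimate of the bistable volume
#'
#' The normalised log-volume \eqn{V_\sigma} of the bistable region is
#' estimated by the fraction of labelled sample points that are bistable
#' (the sample mean of the indicator \eqn{\iota_\sigma}), with a central
#' limit theorem confidence interval
#' \eqn{\hat V_\sigma \pm z_{1-\alpha/2}\, \hat\delta / \sqrt{N}} where
#' \eqn{\hat\delta} is the sample standard deviation of the indicator.
#' `NONGENERIC` points are excluded from numerator and denominator.  When
#' no bistable point is found the interval is the rule-of-three bound
#' `[0, 3/n]` and the estimate is flagged.
#'
#' @param sample A [label_sample()] result.
#' @param sigma One sigma value present in the sample.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `volume_estimate` with fields `v_hat`, `n`,
#'   `ci_low`, `ci_high`, `sigma`, `conf`, `n_bistable`, `degenerate_ci`.
#' @export
estimate_volume <- function(sample, sigma, conf = 0.95) {
  stopifnot(inherits(sample, "labelled_sample"))
  k <- match(as.character(sigma), colnames(sample$labels))
  if (is.na(k)) stop("sigma not present in the labelled sample",
                     call. = FALSE)
  lab <- sample$labels[, k]
  lab <- lab[lab != "NONGENERIC"]
  n <- length(lab)
  if (n < 2L) stop("need at least 2 generic labelled points", call. = FALSE)
  ind <- as.numeric(lab == "BISTABLE")
  v <- mean(ind)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  degenerate <- sum(ind) == 0
  if (degenerate) {
    lo <- 0; hi <- min(1, 3 / n)   # rule of three
  } else {
    hw <- z * stats::sd(ind) / sqrt(n)
    lo <- max(0, v - hw); hi <- min(1, v + hw)
  }
  structure(list(v_hat = v, n = n, ci_low = lo, ci_high = hi,
                 sigma = sigma, conf = conf, n_bistable = sum(ind > 0),
                 degenerate_ci = degenerate,
                 box = sample$box, mode = sample$mode),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf(
    "Bistable volume at sigma = %g: %.4g%% of the box (n = %d, %g%% CI [%.4g%%, %.4g%%])%s\n",
    x$sigma, 100 * x$v_hat, x$n, 100 * x$conf, 100 * x$ci_low,
    100 * x$ci_high,
    if (x$degenerate_ci) " [no bistable point; rule-of-three bound]" else ""))
  invisible(x)
}

#' Volume curve across the sample's sigma grid
#'
#' @param sample A [label_sample()] result.
#' @param conf Confidence level.
#' @return Data frame with one row per sigma: `sigma`, `v_hat`, `ci_low`,
#'   `ci_high`, `n`, `n_bistable`; class `volume_curve`.
#' @export
volume_curve <- function(sample, conf = 0.95) {
  rows <- lapply(sample$sigma, function(s) {
    e <- estimate_volume(sample, s, conf)
    data.frame(sigma = s, v_hat = e$v_hat, ci_low = e$ci_low,
               ci_high = e$ci_high, n = e$n, n_bistable = e$n_bistable)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("volume_curve", "data.frame")
  out
}

#' @export
plot.volume_curve <- function(x, ...) {
  graphics::plot(x$sigma, 100 * x$v_hat, log = "x", type = "b", pch = 16,
                 xlab = expression(sigma),
                 ylab = "bistable volume (% of box)", ...)
  graphics::arrows(x$sigma, 100 * x$ci_low, x$sigma, 100 * x$ci_high,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Solver-backed bistability indicator
#'
#' Returns a closure mapping a matrix of log10 parameter points to a
#' logical vector (`TRUE` = bistable).  `NONGENERIC` points are `NA`.
#' Useful for [estimate_visibility()], [refine_components()] and
#' [vegas_run()], whose geometric machinery is agnostic to where the
#' indicator comes from.
#'
#' @param sigma Substrate-abundance value.
#' @param mode `"weak"` or `"strong"`.
#' @param zeta,lam Totals configuration (defaults \eqn{\zeta = 1},
#'   \eqn{\lambda = \sigma}).
#' @param thresholds A [classifier_thresholds()] object.
#' @return `function(points) -> logical`.
#' @export
bistable_indicator <- function(sigma, mode = "weak", zeta = 1, lam = sigma,
                               thresholds = classifier_thresholds()) {
  force(sigma); force(mode); force(zeta); force(lam); force(thresholds)
  function(points) {
    th <- theta_natural(rbind(points), mode)
    res <- label_batch(th, sigma, lam, zeta, mode, thresholds)
    out <- res[, "n_pos_real"] == 3L
    out[res[, "status"] >= 2L] <- NA
    out
  }
}
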