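# Cross-sigma analyses: the substrate threshold, blinking points, and the
# product-rebinding tradeoff.

#' Scan for the substrate threshold of bistability
#'
#' Labels one common ILR sample at every sigma in `sigma_values`
#' (ascending) and reports the bistable count per sigma together with the
#' smallest sigma at which any bistable point was found.  Below the
#' threshold \eqn{\sigma^*} no bistability is detectable by random
#' sampling.
#'
#' @param box A [sampling_box()].
#' @param n Sample size.
#' @param sigma_values Ascending sigma values.
#' @param seed Integer seed.
#' @param mode `"weak"` or `"strong"`.
#' @return An object of class `threshold_scan`: data frame `counts`
#'   (`sigma`, `n_bistable`, `n_nongeneric`) and `sigma_first_hit` (NA if
#'   no bistable point anywhere).
#' @export
threshold_scan <- function(box, n, sigma_values, seed = 1,
                           mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  sigma_values <- sigma_grid(sigma_values)
  pts <- ilr_sample(n, box, seed)
  lab <- label_sample(pts, sigma_values, mode = mode)
  nb <- colSums(lab$labels == "BISTABLE")
  counts <- data.frame(sigma = sigma_values, n_bistable = as.integer(nb),
                       n_nongeneric = as.integer(lab$nongeneric))
  hit <- which(nb > 0)
  structure(list(counts = counts,
                 sigma_first_hit = if (length(hit))
                   sigma_values[min(hit)] else NA_real_,
                 sample = lab),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  print(x$counts, row.names = FALSE)
  cat(if (is.na(x$sigma_first_hit)) "no bistable point found\n" else
    sprintf("smallest sigma with a bistable point: %g\n",
            x$sigma_first_hit))
  invisible(x)
}

#' Blinking points and their relation to the largest component
#'
#' A parameter point *blinks* at sigma when it is bistable there but
#' monostable at some larger sigma in the grid.  For each sigma the
#' summary counts the bistable points (`n_bistable`), the blinking points
#' (`bp`), those lying outside the sigma-specific largest connected
#' component (`bpsc`), those never inside the largest component at any
#' larger sigma where they are bistable (`bpnl`), and those monostable at
#' the grid's maximal sigma, the operational proxy for asymptotic
#' monostability (`bpam`).  Points with any `NONGENERIC` entry in their
#' profile are excluded (tallied in `n_excluded`).
#'
#' @param sample A [label_sample()] result covering the full sigma grid on
#'   a common point set.
#' @param delta Graph threshold for the per-sigma connectivity graphs
#'   (default 0.15).
#' @param graphs Optional named list of precomputed
#'   [build_spanning_forest()] graphs, one per sigma (names =
#'   `as.character(sigma)`), each built on exactly the bistable subset at
#'   that sigma in sample order.
#' @return An object of class `blinking_summary`: data frame `table` with
#'   columns `sigma`, `n_bistable`, `bp`, `bpsc`, `bpnl`, `bpam`, plus
#'   `n_excluded` and the per-sigma largest-component membership used.
#' @export
blinking_summary <- function(sample, delta = 0.15, graphs = NULL) {
  stopifnot(inherits(sample, "labelled_sample"))
  sig <- sample$sigma
  ns <- length(sig)
  if (ns < 2L) stop("need at least two sigma values", call. = FALSE)
  lab <- sample$labels
  ok <- rowSums(lab == "NONGENERIC") == 0L
  bi <- lab == "BISTABLE"
  # membership of each bistable point in its sigma's largest component
  in_largest <- matrix(FALSE, nrow(lab), ns)
  for (k in seq_len(ns)) {
    members <- which(ok & bi[, k])
    if (length(members) < 1L) next
    g <- if (!is.null(graphs)) graphs[[as.character(sig[k])]] else
      build_spanning_forest(sample$points[members, , drop = FALSE], delta)
    sizes <- tabulate(g$labels)
    in_largest[members, k] <- g$labels == which.max(sizes)
  }
  rows <- lapply(seq_len(ns - 1L), function(k) {
    later <- (k + 1L):ns
    is_bp <- ok & bi[, k] &
      rowSums(lab[, later, drop = FALSE] == "MONOSTABLE") > 0L
    bp_idx <- which(is_bp)
    bpsc <- sum(!in_largest[bp_idx, k])
    bpnl <- sum(vapply(bp_idx, function(i)
      !any(in_largest[i, later]), logical(1)))
    bpam <- sum(lab[bp_idx, ns] == "MONOSTABLE")
    data.frame(sigma = sig[k], n_bistable = sum(ok & bi[, k]),
               bp = length(bp_idx), bpsc = bpsc, bpnl = bpnl, bpam = bpam)
  })
  structure(list(table = do.call(rbind, rows),
                 n_excluded = sum(!ok),
                 sigma_max = sig[ns]),
            class = "blinking_summary")
}

#' @export
print.blinking_summary <- function(x, ...) {
  cat(sprintf(
    "Blinking summary (asymptotic proxy: monostable at sigma = %g; %d points excluded as nongeneric)\n",
    x$sigma_max, x$n_excluded))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Product-rebinding tradeoff bound
#'
#' Under weak irreversibility bistability is confined to the region where
#' the product \eqn{\epsilon_2 \phi_0} of the two rebinding parameters is
#' below a sigma-dependent constant.  The empirical bound
#' \eqn{\hat K(\sigma)} is the maximum of \eqn{\theta_5 \theta_6} over the
#' bistable points of the sample; by construction no bistable point
#' violates it.
#'
#' @param sample A [label_sample()] result in weak mode.
#' @param sigma One sigma value present in the sample.
#' @return An object of class `tradeoff_bound`: `k_hat`, `n_bistable`, the
#'   bistable `(eps2, phi0)` scatter table, and `count_above(c)`, a
#'   function giving the number of bistable points with
#'   \eqn{\epsilon_2\phi_0 > c}.
#' @export
tradeoff_bound <- function(sample, sigma) {
  stopifnot(inherits(sample, "labelled_sample"))
  if (sample$mode != "weak")
    stop("the rebinding product is identically zero in strong mode",
         call. = FALSE)
  k <- match(as.character(sigma), colnames(sample$labels))
  if (is.na(k)) stop("sigma not present in the labelled sample",
                     call. = FALSE)
  sel <- sample$labels[, k] == "BISTABLE"
  eps2 <- 10^sample$points[sel, 5L]
  phi0 <- 10^sample$points[sel, 6L]
  prod <- eps2 * phi0
  structure(list(sigma = sigma,
                 k_hat = if (length(prod)) max(prod) else NA_real_,
                 n_bistable = sum(sel),
                 scatter = data.frame(eps2 = eps2, phi0 = phi0),
                 count_above = function(c) sum(prod > c)),
            class = "tradeoff_bound")
}

#' @export
print.tradeoff_bound <- function(x, ...) {
  cat(sprintf(
    "Rebinding tradeoff at sigma = %g: K_hat = max eps2*phi0 = %.4g over %d bistable points\n",
    x$sigma, x$k_hat, x$n_bistable))
  invisible(x)
}

#' @export
plot.tradeoff_bound <- function(x, ...) {
  graphics::plot(x$scatter$eps2, x$scatter$phi0, log = "xy", pch = ".",
                 xlab = expression(epsilon[2]), ylab = expression(phi[0]),
                 main = sprintf("sigma = %g, K_hat = %.3g", x$sigma,
                                x$k_hat), ...)
  graphics::curve(x$k_hat / x, add = TRUE, col = "red")
  invisible(x)
}
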