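# VEGAS adaptive importance sampling over the p = 1 box.
#
# Each axis of [-1, 1] (log10 coordinates) carries M bins.  At every
# iteration the accumulated bistable set is projected onto each axis, the
# bin frequencies are smoothed as f <- ceil(K * f / #set) + 1 so no bin is
# ever empty, and the axis is re-partitioned so every new bin carries an
# equal share of the smoothed frequency mass: bins shrink where bistable
# density is high.  New coordinates are then assigned to bins by the
# stratified rule I(n, r) with a single uniform r per axis and sampled
# uniformly within their bin, so sampling density is proportional to
# 1/bin-length, concentrating on high-density regions.

#' Create a VEGAS grid
#'
#' @param dimension Number of axes (8 weak, 6 strong).
#' @param M Bins per axis (default 50).
#' @param K Smoothing factor (default 1000).
#' @return An object of class `vegas_grid`: `edges` is a `(M+1)` x
#'   `dimension` matrix of strictly increasing bin edges from -1 to 1.
#' @export
vegas_grid <- function(dimension = 8, M = 50, K = 1000) {
  stopifnot(M >= 2, K >= 1, dimension >= 1)
  structure(list(edges = matrix(seq(-1, 1, length.out = M + 1),
                                M + 1, dimension),
                 M = as.integer(M), K = as.integer(K), iteration = 0L),
            class = "vegas_grid")
}

#' @export
print.vegas_grid <- function(x, ...) {
  cat(sprintf("VEGAS grid: %d axes x %d bins, smoothing K = %d, iteration %d\n",
              ncol(x$edges), x$M, x$K, x$iteration))
  invisible(x)
}

# smoothed per-axis frequencies of the projected set on the current bins
vegas_smoothed_freq <- function(values, edges, K) {
  M <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  f <- tabulate(idx, nbins = M)
  ceiling(K * f / length(values)) + 1L
}

# equal-mass re-partition: new edges place an equal share of the smoothed
# frequency mass in every bin (piecewise-linear inverse CDF)
vegas_rebin <- function(edges, freq) {
  M <- length(edges) - 1L
  cum <- c(0, cumsum(freq))
  targets <- seq(0, cum[M + 1L], length.out = M + 1L)
  new_edges <- stats::approx(cum, edges, xout = targets, ties = "ordered")$y
  new_edges[1L] <- edges[1L]
  new_edges[M + 1L] <- edges[M + 1L]
  # guard strict monotonicity against rounding
  for (i in 2:(M + 1L))
    if (new_edges[i] <= new_edges[i - 1L])
      new_edges[i] <- new_edges[i - 1L] +
        .Machine$double.eps * max(1, abs(new_edges[i - 1L]))
  new_edges
}

#' One VEGAS iteration
#'
#' Updates every axis of the grid from the projections of the current
#' bistable set, then draws `n_new` points: per axis, point `n` is assigned
#' to the bin `I(n, r)` whose index is the least `i` with
#' `i/M >= (r + n)/N` (one shared uniform `r` per axis) and its coordinate
#' is sampled uniformly within that bin.
#'
#' @param bistable_points Matrix of log10 coordinates of the current
#'   bistable set (non-empty).
#' @param grid A [vegas_grid()].
#' @param n_new Number of points to draw.
#' @param seed Integer seed.
#' @return List with `points` (`n_new` x `d` log10 matrix) and the updated
#'   `grid`.
#' @export
vegas_step <- function(bistable_points, grid, n_new, seed = 1) {
  stopifnot(inherits(grid, "vegas_grid"))
  bistable_points <- rbind(bistable_points)
  if (nrow(bistable_points) == 0L)
    stop("empty bistable set: gather an initial set by ILR sampling first",
         call. = FALSE)
  d <- ncol(grid$edges)
  if (ncol(bistable_points) != d)
    stop("dimension mismatch between points and grid", call. = FALSE)
  M <- grid$M
  edges <- grid$edges
  for (j in seq_len(d)) {
    f <- vegas_smoothed_freq(bistable_points[, j], edges[, j], grid$K)
    edges[, j] <- vegas_rebin(edges[, j], f)
  }
  pts <- with_seed(seed, {
    out <- matrix(0, n_new, d)
    for (j in seq_len(d)) {
      r <- stats::runif(1)
      bin <- pmin(M, pmax(1L, ceiling(M * (r + seq_len(n_new)) / n_new)))
      lo <- edges[bin, j]
      hi <- edges[bin + 1L, j]
      out[, j] <- stats::runif(n_new, lo, hi)
    }
    out
  })
  colnames(pts) <- colnames(bistable_points)
  grid$edges <- edges
  grid$iteration <- grid$iteration + 1L
  list(points = pts, grid = grid)
}

#' Run the VEGAS enrichment loop
#'
#' Repeats [vegas_step()] `iterations` times: draw `n_per_iter` points from
#' the adapted grid, keep the bistable ones (per the indicator), and fold
#' them into the accumulated set.  Reports the enrichment factor — the
#' bistable fraction among VEGAS draws relative to a reference (e.g. ILR)
#' fraction.
#'
#' @param initial_bistable Matrix of log10 coordinates seeding the
#'   adaptation (e.g. the bistable subset of an ILR sample).
#' @param iterations Number of iterations `T` (0 returns the seed set
#'   unchanged).
#' @param n_per_iter Points drawn per iteration.
#' @param indicator Function mapping a log10 point matrix to a logical
#'   bistable flag, e.g. [bistable_indicator()]; `NA` flags (nongeneric
#'   points) count as not bistable.
#' @param seed Integer seed.
#' @param reference_fraction Optional baseline bistable fraction for the
#'   enrichment factor.
#' @param grid A [vegas_grid()]; defaults to a fresh uniform grid matching
#'   the seed set's dimension.
#' @return An object of class `vegas_run`: `bistable` (accumulated set),
#'   `grid`, `n_drawn`, `n_bistable_new`, `fraction`, `enrichment`.
#' @export
vegas_run <- function(initial_bistable, iterations, n_per_iter, indicator,
                      seed = 1, reference_fraction = NULL,
                      grid = NULL) {
  initial_bistable <- rbind(initial_bistable)
  if (nrow(initial_bistable) == 0L)
    stop("empty bistable set: gather an initial set by ILR sampling first",
         call. = FALSE)
  if (is.null(grid)) grid <- vegas_grid(ncol(initial_bistable))
  acc <- initial_bistable
  n_drawn <- 0L
  n_bi <- 0L
  if (iterations > 0) for (t in seq_len(iterations)) {
    st <- vegas_step(acc, grid, n_per_iter, derive_seed(seed, t))
    grid <- st$grid
    bi <- indicator(st$points)
    bi[is.na(bi)] <- FALSE
    n_drawn <- n_drawn + nrow(st$points)
    n_bi <- n_bi + sum(bi)
    if (any(bi)) acc <- rbind(acc, st$points[bi, , drop = FALSE])
  }
  frac <- if (n_drawn > 0) n_bi / n_drawn else NA_real_
  structure(list(bistable = acc, grid = grid, n_drawn = n_drawn,
                 n_bistable_new = n_bi, fraction = frac,
                 enrichment = if (!is.null(reference_fraction) &&
                                  n_drawn > 0)
                   frac / reference_fraction else NA_real_),
            class = "vegas_run")
}

#' @export
print.vegas_run <- function(x, ...) {
  cat(sprintf(
    "VEGAS run: %d new draws, %d bistable (fraction %.4g)%s; accumulated set %d\n",
    x$n_drawn, x$n_bistable_new, x$fraction,
    if (is.finite(x$enrichment))
      sprintf(", enrichment %.3gx", x$enrichment) else "",
    nrow(x$bistable)))
  invisible(x)
}
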