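# Shape of the bistable region: Delta selection, spanning-forest
# connectivity, component refinement and the K-fold visibility ratio.

#' Connectivity configuration
#'
#' @param delta Euclidean distance threshold in log10 coordinates
#'   (default 0.15, the value used for all connectivity analyses).
#' @param coverage Target probability that a sample point has a neighbour
#'   within delta, used by [choose_delta()] (default 0.99).
#' @param ann_epsilon Nearest-neighbour approximation slack honoured during
#'   refinement; the search used here is exact, which satisfies the
#'   `(1+epsilon)` contract trivially.
#' @param segment_step Sub-interval length for segment filling during
#'   refinement, as a fraction of delta (default 0.98).
#' @return An object of class `connectivity_config`.
#' @export
connectivity_config <- function(delta = 0.15, coverage = 0.99,
                                ann_epsilon = 0.001, segment_step = 0.98) {
  delta <- as.numeric(delta); coverage <- as.numeric(coverage)
  ann_epsilon <- as.numeric(ann_epsilon)
  segment_step <- as.numeric(segment_step)
  stopifnot(delta > 0, coverage > 0, coverage < 1,
            segment_step > 0, segment_step <= 1)
  structure(list(delta = delta, coverage = coverage,
                 ann_epsilon = ann_epsilon, segment_step = segment_step),
            class = "connectivity_config")
}

#' Sample-size-aware choice of the graph threshold Delta
#'
#' Chooses Delta so that a point of an ILR sample of the given effective
#' size has a neighbour within Delta with the target coverage probability:
#' \deqn{\Delta = \left[\frac{24 V_H (1 - (1-c)^{1/(N'-1)})}{\pi^4}
#' \right]^{1/8},}
#' using the volume \eqn{\pi^4 \Delta^8 / 24} of the 8-ball.
#'
#' @param effective_n Effective sample size \eqn{N'} (at least 2); see
#'   [effective_sample_size()] for enriched samples.
#' @param v_h Log-volume of the box (256 for the p = 1, 8-dimensional box).
#' @param coverage Coverage probability (default 0.99).
#' @return Delta, a log10-space distance.
#' @export
#' @examples
#' choose_delta(4.67e8)          # ~0.17
#' choose_delta(2)               # ~1.68
choose_delta <- function(effective_n, v_h = 256, coverage = 0.99) {
  if (effective_n < 2) stop("effective_n must be at least 2", call. = FALSE)
  (24 * v_h * (1 - (1 - coverage)^(1 / (effective_n - 1))) / pi^4)^(1 / 8)
}

#' Effective sample size of an enriched bistable set
#'
#' An adaptively augmented sample is assigned the ILR-equivalent size
#' \eqn{N' = (\#bistable_{augmented} / \#bistable_{initial}) \times
#' N_{initial}}, scaling the initial ILR sample size proportionally with
#' the increase in bistable points.
#'
#' @param n_bistable_augmented,n_bistable_initial,n_initial Positive counts.
#' @return \eqn{N'}.
#' @export
#' @examples
#' effective_sample_size(3208681, 27508, 4e6)  # ~4.67e8
effective_sample_size <- function(n_bistable_augmented, n_bistable_initial,
                                  n_initial) {
  if (n_bistable_initial <= 0 || n_initial <= 0 || n_bistable_augmented <= 0)
    stop("all counts must be positive", call. = FALSE)
  (n_bistable_augmented / n_bistable_initial) * n_initial
}

#' Build the spanning forest of the Delta-graph
#'
#' The connectivity graph has the bistable points as vertices and an edge
#' between any two within Euclidean distance Delta in log10 coordinates.
#' A spanning forest with the same connected components is built by the
#' queue algorithm — breadth-first search from each unvisited point, adding
#' edges only to yet-unvisited points within Delta — with neighbour
#' queries served by an exact KD-tree.  Edge sets are forest-dependent;
#' only the component partition is contractual.
#'
#' @param points Matrix of log10 coordinates.
#' @param delta Distance threshold (default 0.15).
#' @return An object of class `connectivity_graph`: `points`, `delta`,
#'   integer `labels` (component id per vertex), `edges` (2-column index
#'   matrix), `n_components`.
#' @export
build_spanning_forest <- function(points, delta = 0.15) {
  points <- rbind(points)
  res <- cpp_spanning_forest(points, delta)
  structure(list(points = points, delta = delta,
                 labels = res$labels, edges = res$edges,
                 n_components = if (nrow(points)) max(res$labels) else 0L),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf(
    "Connectivity graph: %d points, Delta = %g, %d components, %d forest edges\n",
    nrow(x$points), x$delta, x$n_components, nrow(x$edges)))
  invisible(x)
}

#' Component statistics of a connectivity graph
#'
#' @param graph A [build_spanning_forest()] result.
#' @return An object of class `component_summary`: `n_points`,
#'   `n_components`, `c1` and `c2` (sizes of the largest and second-largest
#'   components), `n_singletons`, `largest_share_pct`.
#' @export
summarize_components <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  if (nrow(graph$points) == 0L)
    return(structure(list(n_points = 0L, n_components = 0L, c1 = 0L,
                          c2 = 0L, n_singletons = 0L,
                          largest_share_pct = 0),
                     class = "component_summary"))
  sizes <- sort(tabulate(graph$labels), decreasing = TRUE)
  structure(list(n_points = nrow(graph$points),
                 n_components = length(sizes),
                 c1 = sizes[1L],
                 c2 = if (length(sizes) > 1L) sizes[2L] else 0L,
                 n_singletons = sum(sizes == 1L),
                 largest_share_pct = 100 * sizes[1L] / sum(sizes)),
            class = "component_summary")
}

#' @export
print.component_summary <- function(x, ...) {
  cat(sprintf(
    "%d points in %d components; largest %d (%.1f%%), second %d, singletons %d\n",
    x$n_points, x$n_components, x$c1, x$largest_share_pct, x$c2,
    x$n_singletons))
  invisible(x)
}

# interior points of the log-space segment between two rows, t = j/(K+1)
segment_interior <- function(a, b, K) {
  t <- seq_len(K) / (K + 1)
  outer(t, b - a) + rep(a, each = K)
}

#' Refine a connectivity graph by bridging sampling
#'
#' Attempts to connect non-largest components to the largest one: for each
#' non-largest component a random vertex is chosen, its K nearest
#' neighbours in the largest component are found, each connecting segment
#' is subdivided into sub-intervals of length `segment_step * delta`, and
#' the indicator is evaluated at the interior endpoints.  Newfound bistable
#' points are added and the graph rebuilt; K grows between iterations as
#' `j+1` if the second-largest component exceeds 10 vertices, `3(j+1)` if
#' its size is in (3, 10], and `10(j+1)` otherwise.  Iteration stops when
#' the largest-component share is stable (or a single component remains).
#'
#' @param graph A [build_spanning_forest()] result.
#' @param indicator Bistability indicator function (see
#'   [bistable_indicator()]); `NA` results are treated as not bistable.
#' @param config A [connectivity_config()].
#' @param seed Integer seed (random vertex choices).
#' @param max_iter Safety cap on refinement iterations.
#' @param share_tol Stability tolerance on the largest-component share, in
#'   percentage points.
#' @return An object of class `refined_graph`: final `graph`, `newfound`
#'   points, and a per-iteration `history` data frame.
#' @export
refine_components <- function(graph, indicator,
                              config = connectivity_config(),
                              seed = 1, max_iter = 8, share_tol = 1e-6) {
  stopifnot(inherits(graph, "connectivity_graph"))
  newfound <- matrix(numeric(0), 0, ncol(graph$points))
  history <- data.frame()
  j <- 0L
  stable_runs <- 0L
  prev_share <- summarize_components(graph)$largest_share_pct
  repeat {
    cs <- summarize_components(graph)
    if (cs$n_components <= 1L || j >= max_iter) break
    K <- if (cs$c2 > 10) j + 1L else if (cs$c2 > 3) 3L * (j + 1L)
         else 10L * (j + 1L)
    labs <- graph$labels
    sizes <- tabulate(labs)
    largest <- which.max(sizes)
    big <- graph$points[labs == largest, , drop = FALSE]
    probe <- with_seed(derive_seed(seed, j), {
      vapply(setdiff(seq_along(sizes), largest), function(comp) {
        members <- which(labs == comp)
        if (length(members) == 1L) members else sample(members, 1L)
      }, integer(1))
    })
    seg_pts <- list()
    for (p in probe) {
      q <- graph$points[p, ]
      nn <- cpp_knn(big, rbind(q), min(K, nrow(big)))
      for (t in seq_len(ncol(nn$index))) {
        target <- big[nn$index[1, t], ]
        d <- sqrt(sum((target - q)^2))
        nsub <- max(1L, ceiling(d / (config$segment_step * config$delta)))
        if (nsub > 1L)
          seg_pts[[length(seg_pts) + 1L]] <-
            segment_interior(q, target, nsub - 1L)
      }
    }
    j <- j + 1L
    found <- 0L
    if (length(seg_pts)) {
      cand <- unique(do.call(rbind, seg_pts))
      bi <- indicator(cand)
      bi[is.na(bi)] <- FALSE
      found <- sum(bi)
      if (found > 0) {
        newfound <- rbind(newfound, cand[bi, , drop = FALSE])
        graph <- build_spanning_forest(rbind(graph$points,
                                             cand[bi, , drop = FALSE]),
                                       graph$delta)
      }
    }
    share <- summarize_components(graph)$largest_share_pct
    history <- rbind(history,
                     data.frame(iteration = j, K = K,
                                newfound = found, largest_share = share))
    # random probes can fail to find bridging points on a single pass, so
    # stop only after two consecutive iterations without progress
    stable_runs <- if (abs(share - prev_share) <= share_tol)
      stable_runs + 1L else 0L
    if (stable_runs >= 2L) break
    prev_share <- share
  }
  structure(list(graph = graph, newfound = newfound, history = history),
            class = "refined_graph")
}

#' @export
print.refined_graph <- function(x, ...) {
  print(x$graph)
  cat(sprintf("Refinement: %d newfound bistable points over %d iterations\n",
              nrow(x$newfound), nrow(x$history)))
  invisible(x)
}

#' Estimate the K-fold visibility ratio
#'
#' The visibility ratio of a region is the probability that the log-space
#' segment between two random points of the region lies entirely inside
#' it; it equals 1 for convex regions.  The K-fold variant tests only the
#' K equally spaced interior points of each segment and therefore
#' overestimates the true ratio.  `M` ordered pairs are drawn without
#' replacement from the pair population; the confidence interval is
#' \eqn{z\,\hat\delta/\sqrt{M}\cdot\sqrt{1 - M/N}} with \eqn{N} the pair
#' population size (the finite-population correction is dropped when
#' `M/N < 0.01`, as it is negligible there).
#'
#' @param points Matrix of log10 coordinates of region members (endpoints
#'   are known members and are not re-tested).
#' @param indicator Membership indicator function; `NA` counts as outside.
#' @param M Number of pairs (default 500).
#' @param K Interior points per segment (default 10).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return An object of class `visibility_estimate` with `ratio`, `M`, `K`,
#'   `ci_low`, `ci_high`, `fpc_used`.
#' @export
estimate_visibility <- function(points, indicator, M = 500, K = 10,
                                seed = 1, conf = 0.95) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 region points", call. = FALSE)
  N_pop <- as.double(n)^2          # ordered-pair population
  if (M > n * (n - 1)) stop("M exceeds the number of distinct pairs",
                            call. = FALSE)
  pairs <- with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, M, 2L)
    got <- 0L
    while (got < M) {
      i <- sample.int(n, 1L); k <- sample.int(n, 1L)
      if (i == k) next
      key <- paste(i, k)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      out[got, ] <- c(i, k)
    }
    out
  })
  interior <- do.call(rbind, lapply(seq_len(M), function(r)
    segment_interior(points[pairs[r, 1L], ], points[pairs[r, 2L], ], K)))
  bi <- indicator(interior)
  bi[is.na(bi)] <- FALSE
  ok <- vapply(seq_len(M), function(r)
    all(bi[((r - 1L) * K + 1L):(r * K)]), logical(1))
  ratio <- mean(ok)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  fpc_used <- (M / N_pop) >= 0.01
  hw <- z * stats::sd(as.numeric(ok)) / sqrt(M) *
    if (fpc_used) sqrt(1 - M / N_pop) else 1
  structure(list(ratio = ratio, M = M, K = K,
                 ci_low = max(0, ratio - hw), ci_high = min(1, ratio + hw),
                 conf = conf, fpc_used = fpc_used, n_points = n),
            class = "visibility_estimate")
}

#' @export
print.visibility_estimate <- function(x, ...) {
  cat(sprintf(
    "%d-fold visibility ratio: %.4g (M = %d pairs, %g%% CI [%.4g, %.4g])\n",
    x$K, x$ratio, x$M, 100 * x$conf, x$ci_low, x$ci_high))
  invisible(x)
}
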