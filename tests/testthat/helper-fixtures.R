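# Shared test machinery: random parameter draws, synthetic indicator
# regions with known geometry, a brute-force component oracle, and a
# hand-built labelled sample for estimator arithmetic.

random_theta <- function(n, seed, p = 1, mode = "weak") {
  d <- if (mode == "strong") 6L else 8L
  pts <- ilr_sample(n, sampling_box(p, d), seed)
  ptmgeo:::theta_natural(pts, mode)
}

# labelled_sample scaffold around an explicit logical bistable vector
fake_labelled <- function(points, bistable, sigma = 10, mode = "weak") {
  labels <- matrix(ifelse(bistable, "BISTABLE", "MONOSTABLE"),
                   ncol = length(sigma))
  colnames(labels) <- as.character(sigma)
  structure(list(points = points, sigma = sigma, labels = labels,
                 mode = mode, zeta = 1, box = NULL, seed = NULL,
                 nongeneric = stats::setNames(rep(0L, length(sigma)),
                                              as.character(sigma)),
                 retried = stats::setNames(rep(0L, length(sigma)),
                                           as.character(sigma))),
            class = "labelled_sample")
}

# exact indicators of synthetic log-space regions
box_indicator <- function(lo, hi) {
  function(points) {
    points <- rbind(points)
    apply(points, 1L, function(r) all(r >= lo & r <= hi))
  }
}

# 2-D annulus between radii r1 < r2 (non-convex, known geometry)
annulus_indicator <- function(r1, r2) {
  function(points) {
    points <- rbind(points)
    r <- sqrt(rowSums(points^2))
    r >= r1 & r <= r2
  }
}

# two unit boxes joined by a thin bridge along the first axis (dumbbell)
dumbbell_indicator <- function(width = 0.05) {
  function(points) {
    points <- rbind(points)
    x <- points[, 1L]
    others <- points[, -1L, drop = FALSE]
    in_box <- (x >= -1 & x <= -0.5) | (x >= 0.5 & x <= 1)
    in_box <- in_box & apply(abs(others) <= 0.25, 1L, all)
    in_bridge <- x > -0.5 & x < 0.5 &
      apply(abs(others) <= width, 1L, all)
    in_box | in_bridge
  }
}

# brute-force connected components of the Delta-graph (transitive closure)
brute_components <- function(points, delta) {
  n <- nrow(points)
  adj <- as.matrix(stats::dist(points)) < delta
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    comp <- comp + 1L
    frontier <- s
    labels[s] <- comp
    while (length(frontier)) {
      nxt <- which(adj[frontier[1L], ] & labels == 0L)
      labels[nxt] <- comp
      frontier <- c(frontier[-1L], nxt)
    }
  }
  labels
}

# greedy bijective matching of two solution sets; returns the largest
# relative pairing distance (Inf when the sets cannot be matched 1-1)
match_solutions <- function(u1, v1, u2, v2) {
  if (length(u1) != length(u2)) return(Inf)
  used <- rep(FALSE, length(u2))
  worst <- 0
  for (i in seq_along(u1)) {
    d <- Mod(u1[i] - u2) / (1 + Mod(u1[i])) +
      Mod(v1[i] - v2) / (1 + Mod(v1[i]))
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) return(Inf)
    used[j] <- TRUE
    worst <- max(worst, d[j])
  }
  worst
}

# partitions agree up to relabelling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    !anyDuplicated(unique(cbind(a, b))[, 1L]) &&
    !anyDuplicated(unique(cbind(a, b))[, 2L])
}
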