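# Expensive labelled samples shared across test files, computed lazily
# once per test run.  The study conditions (sample sizes, sigma grids,
# seeds) are fixed here and not tuned per test.

.ptmgeo_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (!exists(name, envir = .ptmgeo_cache, inherits = FALSE))
    assign(name, build(), envir = .ptmgeo_cache)
  get(name, envir = .ptmgeo_cache, inherits = FALSE)
}

# 2e5-point ILR sample in H (p = 1, weak) labelled on the main sigma grid
# restricted to sigma >= 2 (the grid used for blinking statistics)
grid_sigma <- function() {
  g <- sigma_grid("MAIN15")
  g[g >= 2]
}

cache_grid_sample <- function() {
  cache_get("grid_sample", function() {
    pts <- ilr_sample(2e5, sampling_box(1, 8), seed = 101)
    label_sample(pts, grid_sigma())
  })
}

# bistable subset of the shared sample at sigma = 10 (log10 coordinates)
cache_bistable10 <- function() {
  lab <- cache_grid_sample()
  lab$points[lab$labels[, "10"] == "BISTABLE", , drop = FALSE]
}

# VEGAS enrichment at sigma = 10 seeded from the ILR bistable set
cache_vegas10 <- function() {
  cache_get("vegas10", function() {
    lab <- cache_grid_sample()
    ref <- mean(lab$labels[, "10"] == "BISTABLE")
    vegas_run(cache_bistable10(), iterations = 2, n_per_iter = 1e5,
              indicator = bistable_indicator(10), seed = 202,
              reference_fraction = ref)
  })
}
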