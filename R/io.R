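# Fixtures, delimited-table and config I/O, and the pipeline driver.

#' The four reference parameter points
#'
#' Four weak-irreversibility parameter points, printed to 10 significant
#' digits, that exemplify the possible stationarity patterns as sigma runs
#' through 3.0, 4.0, 5.0, 7.0, 10: always monostable; bistable from
#' sigma = 5 on; bistable only at sigma = 5; and a "blinking" point,
#' bistable at 4 and 10 but monostable in between.
#'
#' @return A list with `theta` (4 x 8 matrix in theta-order), `sigma`
#'   (the five reference values), and `expected` (4 x 5 character matrix of
#'   stationarity labels).
#' @export
#' @examples
#' fx <- fixture_points()
#' fx$expected["theta3", ]
fixture_points <- function() {
  path <- system.file("extdata", "fixture_points.tsv", package = "ptmgeo",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = "numeric")
  theta <- as.matrix(tab[, -1L])
  rownames(theta) <- paste0("theta", tab$point)
  sigma <- c(3, 4, 5, 7, 10)
  expected <- rbind(
    theta1 = c("MONOSTABLE", "MONOSTABLE", "MONOSTABLE", "MONOSTABLE",
               "MONOSTABLE"),
    theta2 = c("MONOSTABLE", "MONOSTABLE", "BISTABLE", "BISTABLE",
               "BISTABLE"),
    theta3 = c("MONOSTABLE", "MONOSTABLE", "BISTABLE", "MONOSTABLE",
               "MONOSTABLE"),
    theta4 = c("MONOSTABLE", "BISTABLE", "MONOSTABLE", "MONOSTABLE",
               "BISTABLE"))
  colnames(expected) <- as.character(sigma)
  list(theta = theta, sigma = sigma, expected = expected)
}

#' Write / read a delimited table losslessly
#'
#' Tab-delimited text with a header row; numeric columns are written with
#' 17 significant digits so that coordinates round-trip bit-exactly.
#'
#' @param table A data frame or matrix.
#' @param path File path.
#' @return `write_table` returns `path` invisibly; `read_table` returns a
#'   data frame.
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table)
  fmt <- df
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]]))
      fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  out <- tryCatch(
    utils::read.delim(path, check.names = FALSE),
    error = function(e) stop("malformed table file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  out
}

#' Run configuration
#'
#' Bundles every knob of a pipeline run; serialises losslessly to JSON.
#'
#' @param mode `"weak"` or `"strong"`.
#' @param p Box exponent.
#' @param sigma Sigma grid (preset name or numeric vector).
#' @param n Sample size.
#' @param seed Integer seed.
#' @param zeta \eqn{E_{tot}/F_{tot}}.
#' @param lam Either `"sigma"` (the default rule \eqn{\lambda = \sigma}) or
#'   an explicit numeric value.
#' @param thresholds A [classifier_thresholds()] object.
#' @param geometry A [connectivity_config()] object.
#' @param vegas_iterations,vegas_n VEGAS loop size (0 iterations disables
#'   enrichment).
#' @param visibility_pairs,visibility_k Visibility estimator size.
#' @param out_dir Output directory, or `NULL` to keep results in memory
#'   only.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = "weak", p = 1, sigma = "MAIN15", n = 1000,
                       seed = 1, zeta = 1, lam = "sigma",
                       thresholds = classifier_thresholds(),
                       geometry = connectivity_config(),
                       vegas_iterations = 0, vegas_n = 0,
                       visibility_pairs = 0, visibility_k = 10,
                       out_dir = NULL) {
  structure(list(mode = mode, p = as.numeric(p),
                 sigma = sigma_grid(sigma), n = as.numeric(n),
                 seed = as.numeric(seed), zeta = as.numeric(zeta),
                 lam = lam,
                 thresholds = thresholds, geometry = geometry,
                 vegas_iterations = as.numeric(vegas_iterations),
                 vegas_n = as.numeric(vegas_n),
                 visibility_pairs = as.numeric(visibility_pairs),
                 visibility_k = as.numeric(visibility_k),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$geometry <- unclass(x$geometry)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(mode = x$mode, p = x$p, sigma = x$sigma, n = x$n,
             seed = x$seed, zeta = x$zeta, lam = x$lam,
             thresholds = do.call(classifier_thresholds, x$thresholds),
             geometry = do.call(connectivity_config, x$geometry),
             vegas_iterations = x$vegas_iterations, vegas_n = x$vegas_n,
             visibility_pairs = x$visibility_pairs,
             visibility_k = x$visibility_k,
             out_dir = x$out_dir)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Run the full analysis pipeline
#'
#' sample -> label -> volume (every sigma) -> optional VEGAS enrichment ->
#' connectivity -> visibility -> blinking -> tradeoff, all from one seeded
#' configuration.  Stages that need a minimum number of bistable points
#' (connectivity, visibility, tradeoff) are run at the largest sigma of
#' the grid and skipped, with a log entry, when the sample contains too
#' few.  With `out_dir` set, each stage writes delimited tables / JSON
#' summaries tagged with the config hash and seed.
#'
#' @param config A [run_config()].
#' @return An object of class `ptm_run`: list with `config`, `sample`
#'   (labelled), `volumes` (a [volume_curve()]), and — where applicable —
#'   `vegas`, `graph`, `components`, `visibility`, `blinking`, `tradeoff`,
#'   plus a character `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  dim <- if (config$mode == "strong") 6L else 8L
  box <- sampling_box(config$p, dim)
  lam <- if (identical(config$lam, "sigma")) NULL else config$lam

  pts <- ilr_sample(config$n, box, config$seed)
  say("sampled %d points in H_p, p = %g, dim %d, seed %d",
      config$n, config$p, dim, config$seed)
  sample <- label_sample(pts, config$sigma, mode = config$mode,
                         zeta = config$zeta, lam = lam,
                         thresholds = config$thresholds)
  say("labelled across %d sigma values; nongeneric: %s; solver retries: %s",
      length(config$sigma),
      paste(sample$nongeneric, collapse = ","),
      paste(sample$retried, collapse = ","))
  volumes <- volume_curve(sample)

  out <- list(config = config, sample = sample, volumes = volumes)
  s_top <- max(config$sigma)
  bi_top <- sample$labels[, as.character(s_top)] == "BISTABLE"
  bi_pts <- sample$points[bi_top, , drop = FALSE]
  ind <- bistable_indicator(s_top, config$mode, config$zeta,
                            if (is.null(lam)) s_top else lam,
                            config$thresholds)

  if (config$vegas_iterations > 0 && nrow(bi_pts) > 0) {
    out$vegas <- vegas_run(bi_pts, config$vegas_iterations,
                           config$vegas_n, ind,
                           seed = derive_seed(config$seed, 1),
                           reference_fraction = mean(bi_top))
    say("VEGAS: %d draws, %d bistable", out$vegas$n_drawn,
        out$vegas$n_bistable_new)
    bi_pts <- out$vegas$bistable
  }
  if (nrow(bi_pts) >= 2) {
    out$graph <- build_spanning_forest(bi_pts, config$geometry$delta)
    out$components <- summarize_components(out$graph)
    say("connectivity at sigma = %g: %d components",
        s_top, out$components$n_components)
  } else say("connectivity skipped: fewer than 2 bistable points")
  if (config$visibility_pairs > 0 &&
      nrow(bi_pts) * (nrow(bi_pts) - 1) >= config$visibility_pairs) {
    out$visibility <- estimate_visibility(
      bi_pts, ind, M = config$visibility_pairs, K = config$visibility_k,
      seed = derive_seed(config$seed, 2))
    say("visibility ratio %.4g", out$visibility$ratio)
  }
  if (length(config$sigma) >= 2) {
    out$blinking <- blinking_summary(sample,
                                     delta = config$geometry$delta)
    say("blinking points: %d", sum(out$blinking$table$bp))
  }
  if (config$mode == "weak" && any(bi_top))
    out$tradeoff <- tradeoff_bound(sample, s_top)
  out$log <- log

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- sprintf("# config_hash %s seed %d", config_hash(config),
                   config$seed)
    ptab <- data.frame(id = seq_len(nrow(sample$points)), sample$points,
                       check.names = FALSE)
    write_table(ptab, file.path(config$out_dir, "points.tsv"))
    lt <- data.frame(id = seq_len(nrow(sample$labels)), sample$labels,
                     check.names = FALSE)
    write_table(lt, file.path(config$out_dir, "labels.tsv"))
    write_table(volumes, file.path(config$out_dir, "volumes.tsv"))
    summary_json <- list(
      config_hash = config_hash(config), seed = config$seed,
      volumes = as.data.frame(volumes), log = log)
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(tag, log), file.path(config$out_dir, "run.log"))
  }
  class(out) <- "ptm_run"
  out
}

#' @export
print.ptm_run <- function(x, ...) {
  cat("Parameter-geography pipeline run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
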