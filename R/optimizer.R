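#' Default simulation grids
#'
#' `standard_functional_grid()` returns the 300 Naka-Rushton parameter
#' combinations used by the Monte-Carlo study (5 Rmax x 5 C50 x 3 B x 4 n
#' values); `standard_condition_grid()` returns the value lists of the three
#' experimental conditions (6 point counts, 7 repetition counts, 6 trial
#' lengths) whose Cartesian product gives the 252 candidate patterns.
#'
#' @return For the functional grid, a data frame with columns `r_max`,
#'   `c50`, `n`, `b` (one row per combination); for the condition grid, a
#'   named list of value vectors.
#' @export
standard_functional_grid <- function() {
  g <- expand.grid(n = c(1, 2, 3, 6), b = c(1, 2, 4),
                   c50 = c(20, 40, 50, 60, 80), r_max = c(5, 7, 10, 16, 32),
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("r_max", "c50", "n", "b")]
}

#' @rdname standard_functional_grid
#' @export
standard_condition_grid <- function() {
  list(n_points = c(4, 6, 8, 10, 15, 20),
       n_trials = c(1, 2, 4, 8, 16, 32, 64),
       trial_length = c(1, 2, 4, 6, 8, 16))
}

#' Enumerate experimental-condition patterns
#'
#' A pattern is the tuple \{number of contrast points, number of trials,
#' trial length in seconds\}. The enumeration is the full Cartesian product
#' in a fixed, documented order: the point count varies slowest, then the
#' trial count, then the trial length.
#'
#' @param n_points,n_trials,trial_length Value vectors for the three
#'   conditions; default to the standard condition grid.
#' @return A data frame with one row per pattern and columns `n_points`,
#'   `n_trials`, `trial_length`.
#' @examples
#' nrow(enumerate_patterns())  # 252
#' @export
enumerate_patterns <- function(n_points = standard_condition_grid()$n_points,
                               n_trials = standard_condition_grid()$n_trials,
                               trial_length = standard_condition_grid()$trial_length) {
  if (!length(n_points) || !length(n_trials) || !length(trial_length))
    stop_input("all three condition value lists must be non-empty")
  if (any(n_points < 4)) stop_input("patterns need at least 4 contrast points")
  if (any(n_trials < 1) || any(trial_length <= 0))
    stop_input("trial counts and lengths must be positive")
  g <- expand.grid(trial_length = as.double(trial_length),
                   n_trials = as.double(n_trials),
                   n_points = as.double(n_points),
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("n_points", "n_trials", "trial_length")]
}

#' Total recording time of a pattern
#'
#' The time an experiment following a pattern occupies:
#' `n_points * trial_length * n_trials` seconds. For example, 6 contrasts of
#' 2 s repeated 10 times take 6 x 2 x 10 = 120 s.
#'
#' @param pattern A data frame or list with fields `n_points`, `n_trials`,
#'   `trial_length` (vectorized over data-frame rows).
#' @return Recording time(s) in seconds.
#' @export
recording_time <- function(pattern) {
  with(pattern, n_points * trial_length * n_trials)
}

#' Monte-Carlo sweep over functional parameters, patterns and scales
#'
#' For every combination of ground-truth parameters, pattern, scale and
#' replicate: simulate the experiment's mean rates through the
#' Poisson cascade, fit the curve with [fit_crf()] under the data-driven
#' bounds, and score the three error estimators against the known truth.
#' Failed fits are flagged (`ok = FALSE`), never aborting the sweep. The
#' whole sweep is deterministic given `seed`.
#'
#' @param functional_grid Data frame of truths (`r_max`, `c50`, `n`, `b`).
#' @param patterns Data frame of patterns ([enumerate_patterns()]).
#' @param scales Scale ids to sweep (default 1:10).
#' @param n_replicates Replicates per cell (>= 1).
#' @param seed Root seed.
#' @param n_restarts Multistart count passed to [fit_crf()]. The full 500 of
#'   the estimation procedure is rarely needed on simulated data; sweeps
#'   default to 12 plus the deterministic heuristic start.
#' @param noiseless Use exact rates instead of Poisson draws (zero-noise
#'   limit, useful for verification).
#' @param bounds Optional fixed [fit_bounds] overriding the per-dataset
#'   data-driven bounds.
#' @param available Optional measured-contrast list; when given, scale
#'   contrasts are mapped onto it with [map_to_available()].
#' @return A data frame of class `mc_result`, one row per simulation, with
#'   the truth, pattern, `scale_id`, `replicate`, `recording_time_s`, the
#'   three errors (`err_rms_points`, `err_rms_allpoints`, `err_angle_rad`)
#'   and an `ok` flag.
#' @export
run_monte_carlo <- function(functional_grid, patterns, scales = 1:10,
                            n_replicates = 1, seed = 1, n_restarts = 12,
                            noiseless = FALSE, bounds = NULL,
                            available = NULL) {
  stopifnot(is.data.frame(functional_grid), is.data.frame(patterns))
  if (!nrow(functional_grid) || !nrow(patterns) || !length(scales))
    stop_input("empty grid")
  check_number(n_replicates, "n_replicates", lo = 1)

  # contrasts per (scale, n_points), computed once
  pts_values <- sort(unique(patterns$n_points))
  contrast_cache <- list()
  for (s in scales) for (np in pts_values) {
    cc <- generate_scale(s, np)
    if (!is.null(available)) cc <- map_to_available(cc, available)
    contrast_cache[[paste(s, np)]] <- cc
  }

  idx <- expand.grid(replicate = seq_len(n_replicates),
                     scale_id = as.integer(scales),
                     pattern_id = seq_len(nrow(patterns)),
                     combo_id = seq_len(nrow(functional_grid)),
                     KEEP.OUT.ATTRS = FALSE)
  n <- nrow(idx)
  err <- matrix(NA_real_, n, 3)
  ok <- logical(n)
  msg <- character(n)

  for (r in seq_len(n)) {
    f <- functional_grid[idx$combo_id[r], ]
    p <- patterns[idx$pattern_id[r], ]
    truth <- nr_params(f$r_max, f$c50, f$n, f$b)
    cc <- contrast_cache[[paste(idx$scale_id[r], p$n_points)]]
    res <- tryCatch({
      pts <- simulate_rates(truth, cc, p$trial_length, p$n_trials,
                            seed = mix_seed(seed, idx$combo_id[r], idx$pattern_id[r],
                                            idx$scale_id[r], idx$replicate[r]),
                            noiseless = noiseless)
      fit <- fit_crf(pts, bounds = bounds %||% derive_bounds(pts),
                     n_restarts = n_restarts,
                     seed = mix_seed(seed, idx$combo_id[r], idx$pattern_id[r],
                                     idx$scale_id[r], idx$replicate[r], 7L))
      error_triple(fit, truth, cc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg[r] <- conditionMessage(res)
    } else {
      err[r, ] <- res
      ok[r] <- TRUE
    }
  }

  out <- cbind(idx[, c("combo_id", "pattern_id", "scale_id", "replicate")],
               functional_grid[idx$combo_id, , drop = FALSE],
               patterns[idx$pattern_id, , drop = FALSE])
  rownames(out) <- NULL
  out$recording_time_s <- recording_time(out)
  out$err_rms_points <- err[, 1]
  out$err_rms_allpoints <- err[, 2]
  out$err_angle_rad <- err[, 3]
  out$ok <- ok
  out$message <- msg
  structure(out, seed = seed, n_replicates = n_replicates,
            class = c("mc_result", "data.frame"))
}

mc_error_column <- function(error) {
  col <- switch(error,
                rms_points = "err_rms_points",
                rms_allpoints = "err_rms_allpoints",
                angle = "err_angle_rad",
                angle_rad = "err_angle_rad",
                NULL)
  if (is.null(col)) stop_input("unknown error kind: ", error)
  col
}

#' Marginal error profile of one experimental condition
#'
#' Mean and SEM of a chosen error estimator as a function of one condition
#' (number of points, trial length, or number of repetitions), per scale,
#' with the two remaining conditions held at fixed reference values.
#'
#' @param mc An `mc_result` from [run_monte_carlo()].
#' @param condition One of `"points"`, `"length"`, `"repetitions"` (or the
#'   column names `n_points`, `trial_length`, `n_trials`).
#' @param error Error kind: `"rms_points"` (default), `"rms_allpoints"`,
#'   `"angle"`.
#' @param fixed Named list of the reference values at which the other
#'   conditions are held.
#' @return A data frame `scale_id`, `value`, `mean_err`, `sem`, `n`.
#' @export
condition_profiles <- function(mc, condition,
                               error = "rms_points",
                               fixed = list(n_points = 6, trial_length = 2,
                                            n_trials = 10)) {
  stopifnot(inherits(mc, "mc_result"))
  cond <- switch(condition,
                 points = "n_points", n_points = "n_points",
                 length = "trial_length", trial_length = "trial_length",
                 repetitions = "n_trials", n_trials = "n_trials",
                 stop_input("unknown condition: ", condition))
  col <- mc_error_column(error)
  others <- setdiff(c("n_points", "n_trials", "trial_length"), cond)
  keep <- mc$ok
  for (o in others) keep <- keep & mc[[o]] == fixed[[o]]
  d <- mc[keep, ]
  if (!nrow(d))
    stop_input("no sweep rows have ", paste(others, collapse = ", "),
               " at the requested fixed values")
  agg <- stats::aggregate(d[[col]], by = list(scale_id = d$scale_id, value = d[[cond]]),
                          FUN = function(x) c(mean = mean(x),
                                              sem = stats::sd(x) / sqrt(length(x)),
                                              n = length(x)))
  out <- data.frame(scale_id = agg$scale_id, value = agg$value,
                    mean_err = agg$x[, "mean"], sem = agg$x[, "sem"],
                    n = agg$x[, "n"])
  out[order(out$scale_id, out$value), ]
}

#' Aggregate sweep errors per pattern and scale
#'
#' @param mc An `mc_result`.
#' @param error Error kind (see [condition_profiles()]).
#' @return Data frame with the pattern columns, `scale_id`, `mean_err`,
#'   `recording_time_s`, `n`.
#' @export
pattern_error_summary <- function(mc, error = "rms_points") {
  stopifnot(inherits(mc, "mc_result"))
  col <- mc_error_column(error)
  d <- mc[mc$ok, ]
  agg <- stats::aggregate(d[[col]],
                          by = list(pattern_id = d$pattern_id, scale_id = d$scale_id),
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  key <- !duplicated(d$pattern_id)
  pat <- d[key, c("pattern_id", "n_points", "n_trials", "trial_length", "recording_time_s")]
  out <- merge(data.frame(pattern_id = agg$pattern_id, scale_id = agg$scale_id,
                          mean_err = agg$x[, "mean"], n = agg$x[, "n"]),
               pat, by = "pattern_id")
  out[order(out$scale_id, out$pattern_id), ]
}

#' Find the fit-performance versus recording-time trade-off point
#'
#' Patterns are sorted by increasing error; the recording time is taken on a
#' log10 scale (emphasizing its cost) and both curves are min-max normalized
#' to \[0, 1\]. The trade-off (optimization) point is the first pattern, in
#' that order, at which the normalized error meets or exceeds the normalized
#' time. If the curves never cross (or the error curve is flat), the
#' boundary index is returned with `crossed = FALSE` and a warning.
#'
#' @param errors_per_pattern Numeric vector of (mean) errors, one per pattern.
#' @param times_per_pattern Matching vector of recording times in seconds.
#' @param patterns Optional pattern data frame; when given, the selected row
#'   is returned as `pattern`.
#' @return A list: `index` (position in the error-sorted order), `order`
#'   (the sort permutation), `time_s` (raw recording time at the crossing),
#'   `pattern` (row of `patterns` or `NULL`), `crossed`.
#' @export
find_tradeoff_point <- function(errors_per_pattern, times_per_pattern,
                                patterns = NULL) {
  n <- length(errors_per_pattern)
  if (n < 2L) stop_input("need at least 2 patterns")
  if (length(times_per_pattern) != n) stop_input("length mismatch")
  o <- order(errors_per_pattern)
  e <- errors_per_pattern[o]
  lt <- log10(times_per_pattern[o])
  norm <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  degenerate <- diff(range(e)) == 0
  en <- norm(e); tn <- norm(lt)
  hit <- which(en >= tn)
  crossed <- length(hit) > 0 && !degenerate
  idx <- if (length(hit)) hit[1] else n
  if (!crossed)
    warning("error and recording-time curves do not cross; returning the boundary pattern",
            call. = FALSE)
  list(index = idx,
       order = o,
       time_s = times_per_pattern[o][idx],
       pattern = if (!is.null(patterns)) patterns[o[idx], ] else NULL,
       crossed = crossed)
}

#' Trade-off points per scale from a sweep
#'
#' Convenience wrapper: aggregates a sweep with [pattern_error_summary()]
#' and locates the trade-off point of every scale.
#'
#' @param mc An `mc_result`.
#' @param error Error kind.
#' @return Data frame `scale_id`, `index`, `time_s`, `crossed`, plus the
#'   selected pattern columns.
#' @export
tradeoff_by_scale <- function(mc, error = "rms_points") {
  summ <- pattern_error_summary(mc, error)
  out <- lapply(split(summ, summ$scale_id), function(d) {
    tp <- suppressWarnings(
      find_tradeoff_point(d$mean_err, d$recording_time_s,
                          d[, c("n_points", "n_trials", "trial_length")]))
    cbind(data.frame(scale_id = d$scale_id[1], index = tp$index,
                     time_s = tp$time_s, crossed = tp$crossed),
          tp$pattern)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
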