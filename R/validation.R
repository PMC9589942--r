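#' Ground-truth recording container
#'
#' Spike times of one unit organized by direction x contrast x trial, plus
#' the protocol dimensions. This is the object the validation pipeline
#' subsamples: a rich recording (many contrasts, many trials, long trials)
#' from which a reference CRF is fitted and cheaper patterns are drawn.
#'
#' @param unit_id Unit identifier.
#' @param directions Stimulus directions tested, degrees.
#' @param contrasts Sorted measured contrast list, percent.
#' @param trial_length Trial duration, seconds.
#' @param n_trials Trials per (direction, contrast).
#' @param spikes Nested list: `spikes[[d]][[c]]` is a list of `n_trials`
#'   sorted spike-time vectors (seconds from stimulus onset).
#' @return An object of class `crf_recording`.
#' @export
crf_recording <- function(unit_id, directions, contrasts, trial_length,
                          n_trials, spikes) {
  if (is.unsorted(contrasts, strictly = TRUE))
    stop_input("'contrasts' must be sorted without duplicates")
  check_number(trial_length, "trial_length", lo = 0, lo_open = TRUE)
  check_number(n_trials, "n_trials", lo = 1)
  if (length(spikes) != length(directions))
    stop_input("'spikes' must have one entry per direction")
  for (d in seq_along(spikes)) {
    if (length(spikes[[d]]) != length(contrasts))
      stop_input("direction ", directions[d], " is missing contrast entries")
    nt <- lengths(spikes[[d]])
    if (any(nt != n_trials))
      stop_input("direction ", directions[d], " has incomplete trials (expected ",
                 n_trials, ", found ", paste(unique(nt), collapse = "/"), ")")
  }
  structure(list(unit_id = unit_id, directions = as.double(directions),
                 contrasts = as.double(contrasts),
                 trial_length = as.double(trial_length),
                 n_trials = as.integer(n_trials), spikes = spikes),
            class = "crf_recording")
}

#' @export
print.crf_recording <- function(x, ...) {
  cat(sprintf("CRF recording '%s': %d direction(s), %d contrasts, %d trials x %.3g s\n",
              as.character(x$unit_id), length(x$directions), length(x$contrasts),
              x$n_trials, x$trial_length))
  invisible(x)
}

# per-direction mean rate at the maximal contrast, full window
rate_at_max_contrast <- function(rec) {
  ci <- length(rec$contrasts)
  vapply(rec$spikes, function(dir)
    mean(vapply(dir[[ci]], length, numeric(1))) / rec$trial_length,
    numeric(1))
}

#' Inclusion filter for recorded units
#'
#' Units responding too weakly at the maximal contrast cannot support a
#' contrast response fit and are excluded. The rate is taken at the unit's
#' best direction; the boundary is inclusive (exactly 3 spikes/s passes).
#'
#' @param recording A [crf_recording].
#' @param threshold Minimum mean rate at maximal contrast, spikes/s.
#' @return `TRUE` to include, `FALSE` to exclude.
#' @export
unit_inclusion_filter <- function(recording, threshold = 3) {
  stopifnot(inherits(recording, "crf_recording"))
  max(rate_at_max_contrast(recording)) >= threshold
}

#' Fit the ground-truth CRF of one unit
#'
#' The preferred direction is the one maximizing the mean rate at the
#' maximal contrast (ties go to the lowest direction index); the full-data
#' contrast response of that direction is fitted with [fit_crf()] under the
#' data-driven bounds, defining the unit's reference ("theoretical") curve.
#'
#' @param recording A [crf_recording] that passes [unit_inclusion_filter()].
#' @param n_restarts,seed Passed to [fit_crf()].
#' @param bounds Optional explicit [fit_bounds].
#' @return An object of class `crf_ground_truth`: `unit_id`, `params`,
#'   `points`, `direction`, `direction_index`, `fit`.
#' @export
build_ground_truth <- function(recording, n_restarts = 500, seed = NULL,
                               bounds = NULL) {
  stopifnot(inherits(recording, "crf_recording"))
  di <- which.max(rate_at_max_contrast(recording))
  pts <- rates_points(recording$spikes[[di]], recording$contrasts,
                      recording$trial_length)
  fit <- fit_crf(pts, bounds = bounds %||% derive_bounds(pts),
                 n_restarts = n_restarts, seed = seed)
  structure(list(unit_id = recording$unit_id, params = fit$params,
                 points = pts, direction = recording$directions[di],
                 direction_index = di, fit = fit),
            class = "crf_ground_truth")
}

#' Score one pattern against a unit's ground truth by random subsampling
#'
#' Repeatedly draws the experimental conditions a pattern prescribes from
#' the full recording: the pattern's contrasts (via [generate_scale()]
#' mapped onto the measured contrast list), a random subset of trials
#' (without replacement), and the first `trial_length` seconds of each
#' trial (onset-anchored truncation). Each subsample is fitted and the
#' three errors against the reference curve recorded.
#'
#' @param recording A [crf_recording].
#' @param truth The unit's `crf_ground_truth` (or an [nr_params] plus
#'   `direction_index` given separately).
#' @param pattern List/row with `n_points`, `n_trials`, `trial_length`.
#' @param scale_id Contrast scale to use, 1..10.
#' @param n_iterations Number of random subsamples (default 100).
#' @param seed Root seed for the iteration sub-streams.
#' @param n_restarts Multistart count per subsample fit.
#' @param direction_index Direction to subsample; defaults to the truth's
#'   preferred direction.
#' @return An object of class `pattern_score`: the pattern, `scale_id`,
#'   the mapped `contrasts`, a per-iteration error data frame, `mean`,
#'   `sd`, `recording_time_s`.
#' @export
subsample_pattern_errors <- function(recording, truth, pattern, scale_id,
                                     n_iterations = 100, seed = 1,
                                     n_restarts = 25,
                                     direction_index = NULL) {
  stopifnot(inherits(recording, "crf_recording"))
  if (inherits(truth, "crf_ground_truth")) {
    direction_index <- direction_index %||% truth$direction_index
    truth_params <- truth$params
  } else {
    truth_params <- truth
    direction_index <- direction_index %||% 1L
  }
  np <- pattern$n_points; nt <- pattern$n_trials; tl <- pattern$trial_length
  if (np > length(recording$contrasts))
    stop_input("infeasible pattern: n_points = ", np, " exceeds the ",
               length(recording$contrasts), " available contrasts")
  if (nt > recording$n_trials)
    stop_input("infeasible pattern: n_trials = ", nt, " exceeds the ",
               recording$n_trials, " recorded trials")
  if (tl > recording$trial_length + 1e-9)
    stop_input("infeasible pattern: trial_length = ", tl,
               " s exceeds the recorded duration of ", recording$trial_length, " s")

  sel_contrasts <- map_to_available(generate_scale(scale_id, np),
                                    recording$contrasts)
  ci <- match(sel_contrasts, recording$contrasts)
  trains <- recording$spikes[[direction_index]]

  errs <- matrix(NA_real_, n_iterations, 3)
  for (it in seq_len(n_iterations)) {
    local_seed(mix_seed(seed, it), {
      tr <- sample.int(recording$n_trials, nt)
      pts <- rates_points(lapply(ci, function(i) trains[[i]][tr]),
                          sel_contrasts, tl)
      fit <- fit_crf(pts, n_restarts = n_restarts)
      errs[it, ] <- error_triple(fit, truth_params, sel_contrasts)
    })
  }
  errs <- as.data.frame(errs)
  names(errs) <- c("err_rms_points", "err_rms_allpoints", "err_angle_rad")
  pattern_score(pattern, scale_id, errs, contrasts = sel_contrasts,
                unit_id = recording$unit_id)
}

#' Construct a pattern score
#'
#' Low-level constructor used by [subsample_pattern_errors()]; exposed so
#' rankings can also be built from externally computed error tables.
#'
#' @param pattern Pattern list/row (`n_points`, `n_trials`, `trial_length`).
#' @param scale_id Scale id.
#' @param errors Data frame of per-iteration errors with columns
#'   `err_rms_points`, `err_rms_allpoints`, `err_angle_rad`.
#' @param contrasts Optional contrasts used.
#' @param unit_id Optional unit identifier.
#' @export
pattern_score <- function(pattern, scale_id, errors, contrasts = NULL,
                          unit_id = NULL) {
  structure(list(pattern = as.list(pattern)[c("n_points", "n_trials", "trial_length")],
                 scale_id = scale_id,
                 contrasts = contrasts,
                 unit_id = unit_id,
                 errors = errors,
                 mean = colMeans(errors),
                 sd = vapply(errors, stats::sd, numeric(1)),
                 n_iterations = nrow(errors),
                 recording_time_s = recording_time(as.list(pattern))),
            class = "pattern_score")
}

#' @export
print.pattern_score <- function(x, ...) {
  cat(sprintf("Pattern {%g, %g, %g} on scale %s (%d iterations, %g s recording):\n",
              x$pattern$n_points, x$pattern$n_trials, x$pattern$trial_length,
              x$scale_id, x$n_iterations, x$recording_time_s))
  cat(sprintf("  RMS_points %.4g +/- %.4g | RMS_all %.4g +/- %.4g | angle %.4g +/- %.4g rad\n",
              x$mean[1], x$sd[1], x$mean[2], x$sd[2], x$mean[3], x$sd[3]))
  invisible(x)
}

scores_frame <- function(scores, error) {
  col <- mc_error_column(error)
  do.call(rbind, lapply(scores, function(s) {
    data.frame(n_points = s$pattern$n_points, n_trials = s$pattern$n_trials,
               trial_length = s$pattern$trial_length,
               scale_id = s$scale_id %||% NA,
               unit_id = if (is.null(s$unit_id)) NA else as.character(s$unit_id),
               mean_err = unname(s$mean[[col]]),
               recording_time_s = s$recording_time_s)
  }))
}

#' Rank scored patterns and extract the ten best
#'
#' Patterns are ranked from the largest to the smallest mean error; the
#' last ten entries (the error minimizers) are extracted. Ties are broken
#' in favour of the shorter recording time, consistent with the goal of
#' minimizing recording duration.
#'
#' @param scores List of [pattern_score] objects for one unit (typically
#'   one scale).
#' @param error_kind `"rms_points"`, `"rms_allpoints"` or `"angle"`.
#' @return A list with `ranking` (data frame, worst first) and `bottom10`
#'   (the ten smallest-error patterns, best last).
#' @export
rank_patterns <- function(scores, error_kind = "rms_points") {
  d <- scores_frame(scores, error_kind)
  # descending error; among ties longer recordings first, so that the
  # bottom of the ranking holds the shortest-time minimizers
  o <- order(-d$mean_err, -d$recording_time_s)
  ranking <- d[o, ]
  rownames(ranking) <- NULL
  k <- min(10L, nrow(ranking))
  if (nrow(ranking) < 10L)
    warning("fewer than 10 patterns scored; returning all ", nrow(ranking),
            call. = FALSE)
  list(ranking = ranking,
       bottom10 = ranking[seq(nrow(ranking) - k + 1L, nrow(ranking)), ])
}

pattern_key <- function(d) {
  sprintf("{%g, %g, %g}", d$n_points, d$n_trials, d$trial_length)
}

#' Consensus patterns across units, scales and error kinds
#'
#' Counts how often each pattern appears in the per-unit/per-scale bottom-10
#' lists of each error kind. Tier 1 holds patterns present in the top lists
#' of all three error kinds, ordered by total occurrence count (ties to the
#' shorter recording time); tier 2 holds patterns present in exactly two.
#'
#' @param bottom10s Data frame binding bottom-10 rows across units, scales
#'   and error kinds; must carry the pattern columns and an `error_kind`
#'   column.
#' @return A list with `tier1`, `tier2` (data frames with pattern columns,
#'   `n_error_kinds`, `total_count`, `recording_time_s`) and `counts` (the
#'   per-error-kind occurrence table).
#' @export
consensus_patterns <- function(bottom10s) {
  stopifnot(is.data.frame(bottom10s), "error_kind" %in% names(bottom10s))
  if (!nrow(bottom10s)) return(list(tier1 = NULL, tier2 = NULL, counts = NULL))
  b <- bottom10s
  b$key <- pattern_key(b)
  counts <- as.data.frame(table(key = b$key, error_kind = b$error_kind),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  per_key <- split(counts, counts$key)
  meta <- b[!duplicated(b$key),
            c("key", "n_points", "n_trials", "trial_length", "recording_time_s")]
  summ <- do.call(rbind, lapply(per_key, function(d)
    data.frame(key = d$key[1], n_error_kinds = length(unique(d$error_kind)),
               total_count = sum(d$Freq))))
  summ <- merge(summ, meta, by = "key")
  summ <- summ[order(-summ$total_count, summ$recording_time_s), ]
  rownames(summ) <- NULL
  tier <- function(k) {
    d <- summ[summ$n_error_kinds == k, ]
    if (nrow(d)) d else NULL
  }
  list(tier1 = tier(3L), tier2 = tier(2L), counts = counts)
}

#' Growing-window analysis of fit stability
#'
#' Recomputes each unit's CRF from spike counts restricted to `[0, w)` for a
#' grid of window lengths `w`, fits the curve, and expresses the three
#' errors against the unit's full-window reference as percentages
#' ([percent_variation()]; the RMS errors are referenced to the mean
#' theoretical response of the unit, the angle to pi/2). Cohort means and
#' bootstrap confidence intervals (resampling units with replacement) are
#' returned per window.
#'
#' @param recordings List of [crf_recording] objects.
#' @param truths Matching list of `crf_ground_truth` objects.
#' @param window_grid Window lengths in seconds, each in
#'   `(0, trial_length]`.
#' @param n_bootstrap Bootstrap iterations for the CI of the cohort mean.
#' @param seed Seed for the bootstrap resampling.
#' @param n_restarts Multistart count per window fit.
#' @param ci_level Confidence level (default 0.95).
#' @return A data frame `window_s`, `metric`, `mean_pct`, `ci_lo`, `ci_hi`;
#'   the per-unit percent errors are attached as attribute `per_unit`.
#' @export
dynamic_window_errors <- function(recordings, truths, window_grid,
                                  n_bootstrap = 1000, seed = 1,
                                  n_restarts = 25, ci_level = 0.95) {
  stopifnot(length(recordings) == length(truths), length(recordings) >= 1)
  for (rec in recordings) {
    if (any(window_grid <= 0) || any(window_grid > rec$trial_length + 1e-9))
      stop_input("window grid must lie in (0, trial_length]")
  }
  n_u <- length(recordings)
  metrics <- c("rms_points", "rms_allpoints", "angle")
  arr <- array(NA_real_, c(n_u, length(window_grid), 3),
               dimnames = list(NULL, NULL, metrics))
  for (u in seq_len(n_u)) {
    rec <- recordings[[u]]; tr <- truths[[u]]
    trains <- rec$spikes[[tr$direction_index]]
    ref_rms <- mean_response(tr$params)
    for (w in seq_along(window_grid)) {
      pts <- rates_points(trains, rec$contrasts, window_grid[w])
      fit <- fit_crf(pts, n_restarts = n_restarts,
                     seed = mix_seed(seed, u, w))
      e <- error_triple(fit, tr$params, rec$contrasts)
      arr[u, w, ] <- c(percent_variation(e[1], ref_rms),
                       percent_variation(e[2], ref_rms),
                       percent_variation(e[3], pi / 2))
    }
  }
  alpha <- (1 - ci_level) / 2
  rows <- local_seed(mix_seed(seed, 999L), {
    out <- list()
    for (w in seq_along(window_grid)) for (m in seq_along(metrics)) {
      x <- arr[, w, m]
      if (n_u == 1L) {
        ci <- c(x, x)
      } else {
        bs <- vapply(seq_len(n_bootstrap),
                     function(i) mean(x[sample.int(n_u, n_u, replace = TRUE)]),
                     numeric(1))
        ci <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(window_s = window_grid[w],
                                            metric = metrics[m],
                                            mean_pct = mean(x),
                                            ci_lo = ci[1], ci_hi = ci[2])
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "per_unit") <- arr
  res
}
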