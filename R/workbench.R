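#' Build a run configuration
#'
#' A validated bag of settings for the two study orchestrators. Every
#' stochastic step derives its sub-stream from the single `seed`, and the
#' whole configuration is echoed into the output manifest so any report can
#' be reproduced from the manifest alone.
#'
#' @param study `"theoretical"`, `"validation"` or `"dynamic"`.
#' @param ... Study-specific fields, see [run_theoretical_study()] and
#'   [run_validation_study()].
#' @param seed Root seed.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(study = c("theoretical", "validation", "dynamic"),
                       ..., seed = 1L, out_dir = NULL) {
  study <- match.arg(study)
  cfg <- c(list(study = study, seed = as.integer(seed), out_dir = out_dir),
           list(...))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with at least a `study` field.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$study)) stop_input("config file lacks a 'study' field")
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore the exponent's name
  fix_n <- function(x) { names(x)[names(x) %in% c("FALSE", "no")] <- "n"; x }
  for (f in c("functional_grid", "truth_values"))
    if (!is.null(y[[f]])) y[[f]] <- fix_n(y[[f]])
  # functional_grid in a config file is the value lists, crossed into combos;
  # patterns are explicit tuples given as parallel lists
  if (!is.null(y$functional_grid))
    y$functional_grid <- expand.grid(y$functional_grid, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(y$patterns)) y$patterns <- as.data.frame(y$patterns)
  do.call(run_config, y)
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the theoretical study
#'
#' Orchestrates the simulation arm: enumerate the condition patterns, run
#' the Monte-Carlo sweep over the functional grid and scales, aggregate
#' per-pattern errors, and locate the fit-performance/recording-time
#' trade-off point of every scale. When `out_dir` is set, writes
#' `mc_results.csv`, `tradeoff.json` and `manifest.json`.
#'
#' Config fields (all optional): `functional_grid` (data frame; default the
#' standard 300-combination grid), `conditions` (list of the three value
#' vectors; default the standard 252-pattern grid), `scales`,
#' `n_replicates`, `n_restarts`, `error`.
#'
#' @param config A `run_config` (or plain list) with `study = "theoretical"`.
#' @return Invisibly, a list: `patterns`, `mc`, `tradeoff`, `manifest`.
#' @export
run_theoretical_study <- function(config) {
  fg <- config$functional_grid %||% standard_functional_grid()
  cond <- config$conditions %||% standard_condition_grid()
  scales <- config$scales %||% 1:10
  n_rep <- config$n_replicates %||% 1L
  n_restarts <- config$n_restarts %||% 12L
  error <- config$error %||% "rms_points"
  if (!is.data.frame(fg) || !nrow(fg))
    stop_input("functional grid is empty")
  patterns <- enumerate_patterns(cond$n_points, cond$n_trials, cond$trial_length)

  mc <- run_monte_carlo(fg, patterns, scales = scales, n_replicates = n_rep,
                        seed = config$seed %||% 1L, n_restarts = n_restarts,
                        noiseless = isTRUE(config$noiseless))
  tradeoff <- tradeoff_by_scale(mc, error = error)
  manifest <- list(study = "theoretical", seed = config$seed %||% 1L,
                   n_patterns = nrow(patterns),
                   n_functional_combos = nrow(fg),
                   scales = scales, n_replicates = n_rep,
                   n_restarts = n_restarts, error = error,
                   n_failed_fits = sum(!mc$ok),
                   package_version = as.character(utils::packageVersion("crfdk")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(mc), file.path(config$out_dir, "mc_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tradeoff, file.path(config$out_dir, "tradeoff.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(config$out_dir, manifest)
  }
  invisible(list(patterns = patterns, mc = mc, tradeoff = tradeoff,
                 manifest = manifest))
}

#' Run the validation study
#'
#' Orchestrates the empirical arm on a cohort of rich recordings (real or
#' synthetic): apply the inclusion filter, fit each unit's ground-truth
#' curve, score every requested pattern x scale by random subsampling, rank
#' per unit and error kind, and assemble the consensus pattern lists.
#' Optionally runs the growing-window analysis. When `out_dir` is set,
#' writes `pattern_scores.csv`, `consensus.json`, `windows.csv` (if
#' requested) and `manifest.json`.
#'
#' Config fields: `cohort` (a `crf_cohort`) or `spikes_csv` + `spikes_meta`
#' (paths for [read_cohort()]); `patterns` (data frame; required);
#' `scales` (default 1:10); `n_iterations` (default 100); `n_restarts`;
#' `windows` (optional window grid for the dynamic analysis);
#' `n_bootstrap`.
#'
#' @param config A `run_config` (or plain list) with `study = "validation"`.
#' @return Invisibly, a list: `included_units`, `truths`, `scores`
#'   (data frame of per-unit/pattern/scale mean errors), `consensus`,
#'   `windows` (or `NULL`), `manifest`.
#' @export
run_validation_study <- function(config) {
  cohort <- config$cohort %||% {
    if (is.null(config$spikes_csv))
      stop_input("config needs either 'cohort' or 'spikes_csv' + 'spikes_meta'")
    read_cohort(config$spikes_csv, config$spikes_meta)
  }
  patterns <- config$patterns
  if (is.null(patterns) || !nrow(patterns))
    stop_input("config needs a non-empty 'patterns' data frame")
  scales <- config$scales %||% 1:10
  n_iter <- config$n_iterations %||% 100L
  n_restarts <- config$n_restarts %||% 25L
  seed <- config$seed %||% 1L
  gt_restarts <- config$ground_truth_restarts %||% 100L

  keep <- vapply(cohort$units, unit_inclusion_filter, logical(1))
  units <- cohort$units[keep]
  if (!length(units)) stop_input("empty cohort: no unit passes the inclusion filter")
  truths <- lapply(seq_along(units), function(u)
    build_ground_truth(units[[u]], n_restarts = gt_restarts,
                       seed = mix_seed(seed, 5000L, u)))

  kinds <- c("rms_points", "rms_allpoints", "angle")
  score_rows <- list()
  bottom_rows <- list()
  for (u in seq_along(units)) {
    for (s in scales) {
      scores <- lapply(seq_len(nrow(patterns)), function(p)
        subsample_pattern_errors(units[[u]], truths[[u]], patterns[p, ], s,
                                 n_iterations = n_iter,
                                 seed = mix_seed(seed, u, s, p),
                                 n_restarts = n_restarts))
      for (k in kinds) {
        rk <- suppressWarnings(rank_patterns(scores, k))
        b <- rk$bottom10
        b$error_kind <- k
        b$scale_id <- s
        bottom_rows[[length(bottom_rows) + 1L]] <- b
        if (k == kinds[1]) {
          full <- rk$ranking
          for (kk in kinds)
            full[[paste0("mean_", kk)]] <- vapply(
              seq_len(nrow(full)), function(i) {
                j <- which(vapply(scores, function(x)
                  x$pattern$n_points == full$n_points[i] &&
                  x$pattern$n_trials == full$n_trials[i] &&
                  x$pattern$trial_length == full$trial_length[i], logical(1)))[1]
                unname(scores[[j]]$mean[[mc_error_column(kk)]])
              }, numeric(1))
          score_rows[[length(score_rows) + 1L]] <- full
        }
      }
    }
  }
  scores_tab <- do.call(rbind, score_rows)
  consensus <- consensus_patterns(do.call(rbind, bottom_rows))

  windows <- NULL
  if (!is.null(config$windows)) {
    windows <- dynamic_window_errors(units, truths, config$windows,
                                     n_bootstrap = config$n_bootstrap %||% 1000L,
                                     seed = mix_seed(seed, 7000L),
                                     n_restarts = n_restarts)
  }

  manifest <- list(study = "validation", seed = seed,
                   n_units_input = length(cohort$units),
                   n_units_included = length(units),
                   n_patterns = nrow(patterns), scales = scales,
                   n_iterations = n_iter, n_restarts = n_restarts,
                   recording_times_s = unique(sort(recording_time(patterns))),
                   windows = config$windows,
                   package_version = as.character(utils::packageVersion("crfdk")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores_tab, file.path(config$out_dir, "pattern_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(consensus[c("tier1", "tier2")],
                         file.path(config$out_dir, "consensus.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(windows))
      utils::write.csv(as.data.frame(windows),
                       file.path(config$out_dir, "windows.csv"), row.names = FALSE)
    write_manifest(config$out_dir, manifest)
  }
  invisible(list(included_units = vapply(units, function(r) as.character(r$unit_id), ""),
                 truths = truths, scores = scores_tab, consensus = consensus,
                 windows = windows, manifest = manifest))
}
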