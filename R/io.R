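#' Flatten recordings to a spike table
#'
#' The interchange format is a flat table with one row per spike:
#' `unit_id`, `direction_deg`, `contrast_pct`, `trial_idx`, `spike_time_s`.
#' Trials without spikes contribute no rows; the protocol dimensions travel
#' in the metadata sidecar (see [write_cohort()]).
#'
#' @param x A `crf_cohort` or a single [crf_recording].
#' @return A data frame.
#' @export
as_spike_table <- function(x) {
  recs <- if (inherits(x, "crf_cohort")) x$units
          else if (inherits(x, "crf_recording")) list(x)
          else stop_input("expected a crf_cohort or crf_recording")
  do.call(rbind, lapply(recs, function(rec) {
    rows <- list()
    for (d in seq_along(rec$directions)) for (ci in seq_along(rec$contrasts)) {
      trains <- rec$spikes[[d]][[ci]]
      ns <- lengths(trains)
      if (sum(ns) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = as.character(rec$unit_id),
        direction_deg = rec$directions[d],
        contrast_pct = rec$contrasts[ci],
        trial_idx = rep.int(seq_along(trains), ns),
        spike_time_s = unlist(trains, use.names = FALSE))
    }
    do.call(rbind, rows)
  }))
}

spike_table_columns <- c("unit_id", "direction_deg", "contrast_pct",
                         "trial_idx", "spike_time_s")

#' Write and read a cohort as spike-table CSV plus JSON metadata
#'
#' `write_cohort()` writes the spike table to `csv_path` and a JSON sidecar
#' (protocol dimensions, unit list, and -- for synthetic cohorts -- the
#' ground-truth parameters) to `meta_path`. `read_cohort()` reconstructs the
#' `crf_cohort`, including empty trials, from the two files.
#'
#' @param cohort A `crf_cohort`.
#' @param csv_path,meta_path File paths.
#' @return `read_cohort` returns a `crf_cohort` (with `truth = NULL` when
#'   the sidecar carries none).
#' @export
write_cohort <- function(cohort, csv_path, meta_path) {
  stopifnot(inherits(cohort, "crf_cohort"))
  utils::write.csv(as_spike_table(cohort), csv_path, row.names = FALSE)
  s <- cohort$spec
  meta <- list(contrasts = s$contrasts, n_trials = s$n_trials,
               trial_length = s$trial_length, directions = s$directions,
               unit_ids = vapply(cohort$units, function(r) as.character(r$unit_id), ""),
               seed = s$seed,
               adaptation = s$adaptation,
               truth = cohort$truth)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(csv_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  miss <- setdiff(spike_table_columns, names(tab))
  if (length(miss))
    stop_input("spike table is missing column(s): ", paste(miss, collapse = ", "))
  units <- lapply(meta$unit_ids, function(uid) {
    ut <- tab[tab$unit_id == uid, ]
    spikes <- lapply(meta$directions, function(d) {
      dt <- ut[ut$direction_deg == d, ]
      lapply(meta$contrasts, function(cc) {
        ct <- dt[abs(dt$contrast_pct - cc) < 1e-9, ]
        lapply(seq_len(meta$n_trials), function(j)
          sort(ct$spike_time_s[ct$trial_idx == j]))
      })
    })
    crf_recording(uid, meta$directions, meta$contrasts, meta$trial_length,
                  meta$n_trials, spikes)
  })
  adap <- meta$adaptation
  if (!is.null(adap) && !length(adap)) adap <- NULL
  spec <- cohort_spec(n_units = length(units), contrasts = meta$contrasts,
                      n_trials = meta$n_trials, trial_length = meta$trial_length,
                      directions = meta$directions,
                      adaptation = adap,
                      seed = meta$seed %||% 1L)
  truth <- if (!is.null(meta$truth) && length(meta$truth)) as.data.frame(meta$truth) else NULL
  structure(list(units = units, truth = truth, spec = spec),
            class = "crf_cohort")
}
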