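#' The 24-contrast measurement list
#'
#' The contrast percentages of the rich reference protocol emulated by the
#' synthetic cohort generator: 24 values chosen so that every spacing scale
#' can be mapped onto them, each presented 50 times for 4 s in the original
#' protocol.
#'
#' @return Numeric vector of 24 contrast percentages.
#' @export
cat_contrasts <- function() {
  c(0, 3, 6, 8.5, 12, 17, 21, 26, 29, 32, 35, 38, 41, 44, 48,
    53, 57, 63.5, 70, 74.5, 79, 83, 91, 100)
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the dimensions of the reference cat visual-cortex
#' protocol: 42 units, the 24-value contrast list, 50 trials of 4 s per
#' contrast, 12 directions at 30 degree steps. Each unit's true
#' Naka-Rushton parameters are drawn from the standard functional value
#' lists. Firing-rate adaptation is off by default (the theoretical model
#' has none); enabling it multiplies the within-trial rate by
#' `floor + (1 - floor) * exp(-t / tau)`.
#'
#' @param n_units Number of units.
#' @param contrasts Measured contrast list, percent.
#' @param n_trials Trials per (direction, contrast).
#' @param trial_length Trial duration, seconds.
#' @param directions Stimulus directions, degrees.
#' @param truth_values Named list of value vectors (`r_max`, `c50`, `n`,
#'   `b`) from which unit truths are sampled.
#' @param adaptation `NULL` or `list(tau = <s>, floor = <fraction>)`.
#' @param seed Root seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_units = 42,
                        contrasts = cat_contrasts(),
                        n_trials = 50,
                        trial_length = 4,
                        directions = seq(0, 330, by = 30),
                        truth_values = list(r_max = c(5, 7, 10, 16, 32),
                                            c50 = c(20, 40, 50, 60, 80),
                                            n = c(1, 2, 3, 6),
                                            b = c(1, 2, 4)),
                        adaptation = NULL,
                        seed = 1L) {
  check_number(n_units, "n_units", lo = 1)
  check_number(n_trials, "n_trials", lo = 1)
  check_number(trial_length, "trial_length", lo = 0, lo_open = TRUE)
  if (is.unsorted(contrasts, strictly = TRUE))
    stop_input("'contrasts' must be sorted without duplicates")
  stopifnot(all(c("r_max", "c50", "n", "b") %in% names(truth_values)))
  adaptation_profile(adaptation)  # validates
  structure(list(n_units = as.integer(n_units), contrasts = as.double(contrasts),
                 n_trials = as.integer(n_trials), trial_length = as.double(trial_length),
                 directions = as.double(directions), truth_values = truth_values,
                 adaptation = adaptation, seed = as.integer(seed)),
            class = "cohort_spec")
}

# circular tuning factor in (0, 1]; plumbing only (the pipeline never fits
# direction tuning) -- a cosine-lobed profile with a small floor so
# off-preferred directions still spike
tuning_factor <- function(directions, preferred) {
  delta <- (directions - preferred) * pi / 180
  0.1 + 0.9 * ((1 + cos(delta)) / 2)^2
}

#' Generate a synthetic cohort of ground-truth recordings
#'
#' For each unit: true Naka-Rushton parameters are sampled from the spec's
#' value lists, a preferred direction is assigned, the contrast-driven
#' response at off-preferred directions is scaled down by a circular tuning
#' profile (the baseline is direction-independent), and spikes are drawn
#' from the Poisson cascade, optionally thinned by the adaptation profile.
#' Everything is deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec].
#' @return An object of class `crf_cohort`: `units` (list of
#'   [crf_recording]), `truth` (data frame with the per-unit true
#'   parameters and preferred direction), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  profile <- adaptation_profile(spec$adaptation)
  units <- vector("list", spec$n_units)
  truth <- vector("list", spec$n_units)
  for (u in seq_len(spec$n_units)) {
    local_seed(mix_seed(spec$seed, u), {
      tv <- spec$truth_values
      pars <- nr_params(sample(tv$r_max, 1), sample(tv$c50, 1),
                        sample(tv$n, 1), sample(tv$b, 1))
      pref <- sample(spec$directions, 1)
      tf <- tuning_factor(spec$directions, pref)
      base_rates <- evaluate_nre(pars, spec$contrasts)
      spikes <- lapply(seq_along(spec$directions), function(d) {
        rates <- pars$b + tf[d] * (base_rates - pars$b)
        lapply(rates, function(r)
          simulate_contrast_trials(r, spec$trial_length, spec$n_trials, profile))
      })
      units[[u]] <- crf_recording(unit_id = sprintf("unit%03d", u),
                                  directions = spec$directions,
                                  contrasts = spec$contrasts,
                                  trial_length = spec$trial_length,
                                  n_trials = spec$n_trials,
                                  spikes = spikes)
      truth[[u]] <- data.frame(unit_id = sprintf("unit%03d", u),
                               r_max = pars$r_max, c50 = pars$c50,
                               n = pars$n, b = pars$b,
                               preferred_direction = pref)
    })
  }
  structure(list(units = units, truth = do.call(rbind, truth), spec = spec),
            class = "crf_cohort")
}

# vectorized constant-rate trial batch: counts are Poisson, spike times
# uniform on [0, T) given the count (the standard order-statistics property
# of the homogeneous process); optional thinning yields the adaptation
# profile's inhomogeneous rate
simulate_contrast_trials <- function(rate, trial_length, n_trials, profile = NULL) {
  if (rate <= 0) return(replicate(n_trials, numeric(0), simplify = FALSE))
  counts <- stats::rpois(n_trials, rate * trial_length)
  all_t <- stats::runif(sum(counts)) * trial_length
  if (!is.null(profile) && length(all_t))
    keep <- stats::runif(length(all_t)) < profile(all_t)
  else
    keep <- rep(TRUE, length(all_t))
  idx <- rep.int(seq_len(n_trials), counts)
  lapply(seq_len(n_trials), function(j) sort(all_t[keep & idx == j]))
}

#' @export
print.crf_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic CRF cohort: %d units, %d contrasts, %d trials x %g s, %d direction(s)%s\n",
              s$n_units, length(s$contrasts), s$n_trials, s$trial_length,
              length(s$directions),
              if (is.null(s$adaptation)) "" else ", with adaptation"))
  invisible(x)
}
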