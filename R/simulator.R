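#' Stimulus protocol for a simulated contrast experiment
#'
#' Describes one simulated experiment: which contrasts are shown, for how
#' long, and how many times. Presentation order is randomized (as in real
#' protocols, to avoid hysteresis) and stored for provenance; the simulated
#' neuron has no adaptation by default, so the order does not influence the
#' spike statistics.
#'
#' @param contrasts Contrast levels in percent.
#' @param trial_length Trial duration in seconds (> 0).
#' @param n_repetitions Number of repetitions per contrast (>= 1).
#' @param seed Seed used to draw the presentation permutation.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(contrasts, trial_length, n_repetitions, seed = 1L) {
  if (length(contrasts) == 0L) stop_input("'contrasts' is empty")
  if (any(contrasts < 0 | contrasts > 100)) stop_input("contrasts must be in [0, 100]")
  check_number(trial_length, "trial_length", lo = 0, lo_open = TRUE)
  check_number(n_repetitions, "n_repetitions", lo = 1)
  slots <- expand.grid(repetition = seq_len(n_repetitions),
                       contrast_pct = as.double(contrasts))
  order <- local_seed(seed, sample.int(nrow(slots)))
  structure(list(contrasts = as.double(contrasts),
                 trial_length = as.double(trial_length),
                 n_repetitions = as.integer(n_repetitions),
                 order = slots[order, c("contrast_pct", "repetition")],
                 seed = seed),
            class = "stimulus_protocol")
}

# One homogeneous-Poisson spike train on [0, trial_length) at `rate` sp/s,
# by exponential inter-arrival sampling (chunked for speed). An optional
# `profile(t)` in [0, 1] thins the train, yielding an inhomogeneous process
# with instantaneous rate rate * profile(t).
simulate_trial <- function(rate, trial_length, profile = NULL) {
  if (rate <= 0) return(numeric(0))
  lambda <- rate * trial_length
  m <- ceiling(lambda + 5 * sqrt(lambda) + 10)
  t <- cumsum(stats::rexp(m, rate))
  while (t[length(t)] < trial_length) {
    t <- c(t, t[length(t)] + cumsum(stats::rexp(m, rate)))
  }
  t <- t[t < trial_length]
  if (!is.null(profile) && length(t))
    t <- t[stats::runif(length(t)) < profile(t)]
  t
}

#' Simulate a contrast experiment with a nonlinear-Poisson cascade
#'
#' The stimulus contrast is passed through the Naka-Rushton nonlinearity to
#' obtain a firing rate, and spikes are drawn from a Poisson process at that
#' rate. The rate is constant within a trial (no receptive-field temporal
#' dynamics) but varies across stimuli, making the process inhomogeneous
#' over the experiment.
#'
#' @param truth An [nr_params] object, the ground-truth curve.
#' @param protocol A [stimulus_protocol].
#' @param seed Optional seed for reproducible spike trains.
#' @param adaptation Optional firing-rate adaptation, either `NULL` (none) or
#'   a list `list(tau = <s>, floor = <fraction>)`: within each trial the rate
#'   is multiplied by `floor + (1 - floor) * exp(-t / tau)`.
#' @return An object of class `spike_train_set`: per (contrast, repetition)
#'   a sorted vector of spike times in seconds.
#' @export
simulate_experiment <- function(truth, protocol, seed = NULL, adaptation = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  rates <- evaluate_nre(truth, protocol$contrasts)
  profile <- adaptation_profile(adaptation)
  local_seed(seed, {
    spikes <- lapply(seq_along(protocol$contrasts), function(i) {
      lapply(seq_len(protocol$n_repetitions), function(j) {
        simulate_trial(rates[i], protocol$trial_length, profile)
      })
    })
    structure(list(spikes = spikes,
                   contrasts = protocol$contrasts,
                   trial_length = protocol$trial_length,
                   n_repetitions = protocol$n_repetitions,
                   truth = truth, seed = seed,
                   order = protocol$order),
              class = "spike_train_set")
  })
}

adaptation_profile <- function(adaptation) {
  if (is.null(adaptation)) return(NULL)
  stopifnot(is.list(adaptation), !is.null(adaptation$tau), !is.null(adaptation$floor))
  tau <- adaptation$tau; fl <- adaptation$floor
  check_number(tau, "tau", lo = 0, lo_open = TRUE)
  check_number(fl, "floor", lo = 0, hi = 1)
  function(t) fl + (1 - fl) * exp(-t / tau)
}

#' Mean firing rates of a spike train set
#'
#' For each contrast, the rate is the spike count in `[0, window)` divided
#' by `window * n_repetitions`; the SD of the per-trial rates is recorded
#' alongside.
#'
#' @param spikes A `spike_train_set`.
#' @param window Counting window in seconds, defaulting to the full trial.
#' @return A [crf_points] object.
#' @export
mean_firing_rates <- function(spikes, window = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  window <- window %||% spikes$trial_length
  check_number(window, "window", lo = 0, lo_open = TRUE)
  if (window > spikes$trial_length + 1e-12)
    stop_input("'window' exceeds the trial length")
  rates_points(spikes$spikes, spikes$contrasts, window)
}

# shared core: trains[[contrast]][[trial]] -> crf_points over `window`
rates_points <- function(trains, contrasts, window) {
  per <- lapply(trains, function(reps)
    vapply(reps, function(s) sum(s < window), numeric(1)) / window)
  crf_points(contrasts,
             vapply(per, mean, numeric(1)),
             vapply(per, function(r) if (length(r) > 1) stats::sd(r) else 0, numeric(1)))
}

#' Peri-stimulus time histogram
#'
#' Bin spike counts over the trial, average across repetitions and scale to
#' spikes/s. The bin width should divide the trial length approximately;
#' spikes beyond the last full bin are dropped.
#'
#' @param spikes A `spike_train_set`.
#' @param bin Bin width in seconds (default 0.05).
#' @return A matrix (contrast x bin) of class `crf_psth` with attributes
#'   `bin`, `contrasts`, `n_repetitions`.
#' @export
psth <- function(spikes, bin = 0.05) {
  stopifnot(inherits(spikes, "spike_train_set"))
  check_number(bin, "bin", lo = 0, lo_open = TRUE)
  if (bin > spikes$trial_length) stop_input("'bin' exceeds the trial length")
  n_bins <- max(1L, round(spikes$trial_length / bin))
  edges <- seq(0, n_bins * bin, by = bin)
  m <- t(vapply(spikes$spikes, function(reps) {
    counts <- numeric(n_bins)
    for (s in reps) {
      s <- s[s < edges[n_bins + 1L]]
      if (length(s))
        counts <- counts + tabulate(findInterval(s, edges, rightmost.closed = FALSE),
                                    nbins = n_bins)
    }
    counts / (spikes$n_repetitions * bin)
  }, numeric(n_bins)))
  structure(m, bin = bin, contrasts = spikes$contrasts,
            n_repetitions = spikes$n_repetitions,
            class = c("crf_psth", class(m)))
}

#' Simulate trial rates without materializing spike times
#'
#' Count-level shortcut used by the Monte-Carlo sweeps: because the
#' within-trial rate is constant, the spike count of each trial is Poisson
#' with mean `rate * trial_length`, so per-trial rates can be drawn directly
#' without generating individual spike times. Distributionally identical to
#' running [simulate_experiment()] + [mean_firing_rates()], and much faster.
#' With `noiseless = TRUE` the deterministic rates themselves are returned
#' (the infinite-data limit).
#'
#' @param truth An [nr_params] object.
#' @param contrasts Contrast levels, percent.
#' @param trial_length Trial duration, seconds.
#' @param n_trials Repetitions per contrast.
#' @param seed Optional seed.
#' @param noiseless Skip the Poisson draw and return exact rates.
#' @return A [crf_points] object.
#' @export
simulate_rates <- function(truth, contrasts, trial_length, n_trials,
                           seed = NULL, noiseless = FALSE) {
  check_number(trial_length, "trial_length", lo = 0, lo_open = TRUE)
  check_number(n_trials, "n_trials", lo = 1)
  r <- evaluate_nre(truth, contrasts)
  if (noiseless)
    return(crf_points(contrasts, r, rep(0, length(contrasts))))
  local_seed(seed, {
    lam <- r * trial_length
    counts <- matrix(stats::rpois(length(contrasts) * n_trials,
                                  rep(lam, each = n_trials)),
                     nrow = n_trials)
    per <- counts / trial_length
    crf_points(contrasts, colMeans(per),
               if (n_trials > 1) apply(per, 2, stats::sd) else rep(0, length(contrasts)))
  })
}
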