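# Shared fixture builders. Everything is generated in code; no stored data.

# a well-behaved truth used across tests
fixture_truth <- function() nr_params(r_max = 10, c50 = 40, n = 2, b = 1)

# noiseless points from a truth on a default contrast ladder
fixture_points <- function(truth = fixture_truth(),
                           contrasts = c(0, 5, 10, 20, 40, 60, 80, 100)) {
  crf_points(contrasts, evaluate_nre(truth, contrasts))
}

# deterministic recording: explicit spike counts per contrast, evenly
# placed spike times; directions may scale the counts
fixture_recording <- function(counts_per_contrast,
                              contrasts = c(0, 25, 50, 75, 100),
                              trial_length = 4, n_trials = 5,
                              direction_factors = 1, unit_id = "u1") {
  spikes <- lapply(direction_factors, function(fac) {
    lapply(counts_per_contrast, function(k) {
      kk <- round(k * fac)
      lapply(seq_len(n_trials), function(j) {
        if (kk == 0) numeric(0)
        else seq(0, trial_length, length.out = kk + 2L)[2:(kk + 1L)]
      })
    })
  })
  crf_recording(unit_id, seq(0, by = 30, length.out = length(direction_factors)),
                contrasts, trial_length, n_trials, spikes)
}

# draw one ground-truth parameter set from value lists under a seed
local_seed_sample_truth <- function(tv, seed) {
  set.seed(seed)
  nr_params(sample(tv$r_max, 1), sample(tv$c50, 1),
            sample(tv$n, 1), sample(tv$b, 1))
}

# small, fast synthetic cohort (single direction)
fixture_cohort <- function(n_units = 2, n_trials = 10, trial_length = 2,
                           seed = 5, adaptation = NULL) {
  generate_cohort(cohort_spec(n_units = n_units, n_trials = n_trials,
                              trial_length = trial_length, directions = 0,
                              adaptation = adaptation, seed = seed))
}
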