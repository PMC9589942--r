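test_that("the inclusion filter thresholds the rate at maximal contrast", {
  # 11.6 spikes over 4 s = 2.9 sp/s -> excluded; 12 spikes = 3.0 -> included
  low <- fixture_recording(c(0, 2, 4, 8, 11), n_trials = 3)   # 11/4 = 2.75
  expect_false(unit_inclusion_filter(low))
  boundary <- fixture_recording(c(0, 2, 4, 8, 12), n_trials = 3)  # exactly 3.0
  expect_true(unit_inclusion_filter(boundary))
  silent <- fixture_recording(c(0, 0, 0, 0, 0))
  expect_false(unit_inclusion_filter(silent))
  # the best direction is what counts
  multi <- fixture_recording(c(0, 2, 4, 8, 16), direction_factors = c(1, 0.25))
  expect_true(unit_inclusion_filter(multi))
})

test_that("ground truth uses the preferred direction and recovers the truth", {
  # preferred direction = the one maximizing the rate at max contrast
  rec <- fixture_recording(c(0, 2, 6, 10, 14), direction_factors = c(0.4, 1, 0.6))
  gt <- build_ground_truth(rec, n_restarts = 30, seed = 2)
  expect_equal(gt$direction_index, 2)
  expect_equal(gt$direction, 30)
  # all-equal directions: ties go to the lowest index
  tie <- fixture_recording(c(0, 2, 6, 10, 14), direction_factors = c(1, 1))
  expect_equal(build_ground_truth(tie, n_restarts = 10, seed = 2)$direction_index, 1)

  # parameter recovery on Poisson units at the full 50 reps x 4 s protocol
  errs <- vapply(1:8, function(u) {
    spec <- cohort_spec(n_units = 1, directions = 0, seed = 400 + u)
    coh <- generate_cohort(spec)
    truth <- coh$truth
    gt <- build_ground_truth(coh$units[[1]], n_restarts = 40, seed = u,
                             bounds = fit_bounds(100))
    abs(gt$params$r_max - truth$r_max) / truth$r_max
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("subsampling the full recording reproduces the reference fit", {
  coh <- fixture_cohort(n_units = 1, n_trials = 12, trial_length = 2, seed = 8)
  rec <- coh$units[[1]]
  gt <- build_ground_truth(rec, n_restarts = 40, seed = 3)
  ps <- subsample_pattern_errors(rec, gt,
                                 list(n_points = 24, n_trials = 12, trial_length = 2),
                                 scale_id = 1, n_iterations = 2, seed = 4,
                                 n_restarts = 40)
  expect_lt(max(ps$mean), 1e-2)
})

test_that("infeasible patterns are rejected naming the violated dimension", {
  coh <- fixture_cohort(n_units = 1, n_trials = 5, trial_length = 1)
  rec <- coh$units[[1]]
  gt <- list(params = fixture_truth(), direction_index = 1)
  class(gt) <- "crf_ground_truth"
  expect_error(subsample_pattern_errors(rec, gt, list(n_points = 30, n_trials = 2, trial_length = 1), 1),
               "n_points")
  expect_error(subsample_pattern_errors(rec, gt, list(n_points = 6, n_trials = 6, trial_length = 1), 1),
               "n_trials")
  expect_error(subsample_pattern_errors(rec, gt, list(n_points = 6, n_trials = 2, trial_length = 2), 1),
               "trial_length")
})

test_that("richer patterns score better and scoring is seed-stable", {
  coh <- fixture_cohort(n_units = 1, n_trials = 20, trial_length = 2, seed = 12)
  rec <- coh$units[[1]]
  gt <- build_ground_truth(rec, n_restarts = 40, seed = 1)
  rich <- subsample_pattern_errors(rec, gt, list(n_points = 6, n_trials = 16, trial_length = 2),
                                   scale_id = 2, n_iterations = 12, seed = 7, n_restarts = 12)
  poor <- subsample_pattern_errors(rec, gt, list(n_points = 4, n_trials = 4, trial_length = 1),
                                   scale_id = 2, n_iterations = 12, seed = 7, n_restarts = 12)
  expect_lt(rich$mean[["err_rms_points"]], poor$mean[["err_rms_points"]])
  again <- subsample_pattern_errors(rec, gt, list(n_points = 6, n_trials = 16, trial_length = 2),
                                    scale_id = 2, n_iterations = 12, seed = 7, n_restarts = 12)
  expect_identical(rich$errors, again$errors)
})

test_that("ranking extracts the ten smallest errors with time tie-breaks", {
  mk <- function(err, np, nt, tl) {
    pattern_score(list(n_points = np, n_trials = nt, trial_length = tl), 1,
                  data.frame(err_rms_points = err, err_rms_allpoints = err,
                             err_angle_rad = err))
  }
  scores <- lapply(1:20, function(i) mk(i, 4 + i, 10, 2))
  rk <- rank_patterns(scores, "rms_points")
  expect_equal(nrow(rk$bottom10), 10)
  expect_equal(sort(rk$bottom10$mean_err), 1:10)
  expect_equal(rk$ranking$mean_err[1], 20)  # worst first
  # all-equal scores: the ten shortest recordings win
  ties <- lapply(1:15, function(i) mk(1, 4, i, 1))  # time = 4*i
  rkt <- rank_patterns(ties, "rms_points")
  expect_equal(sort(rkt$bottom10$n_trials), 1:10)
})

test_that("consensus tiers count patterns across the three error kinds", {
  row <- function(np, nt, tl, kind) {
    data.frame(n_points = np, n_trials = nt, trial_length = tl,
               recording_time_s = np * nt * tl, error_kind = kind)
  }
  b <- rbind(row(6, 16, 2, "rms_points"), row(6, 16, 2, "rms_allpoints"),
             row(6, 16, 2, "angle"), row(6, 16, 2, "angle"),
             row(4, 20, 2, "rms_points"), row(4, 20, 2, "angle"),
             row(8, 8, 3, "rms_points"))
  cons <- consensus_patterns(b)
  expect_equal(cons$tier1$n_points, 6)
  expect_equal(cons$tier1$total_count, 4)
  expect_equal(unlist(cons$tier2[, c("n_points", "n_trials", "trial_length")]),
               c(n_points = 4, n_trials = 20, trial_length = 2))
  # disjoint histograms: no tier-1 pattern
  d <- rbind(row(4, 4, 1, "rms_points"), row(6, 6, 1, "rms_allpoints"),
             row(8, 8, 1, "angle"))
  cons2 <- consensus_patterns(d)
  expect_null(cons2$tier1)
  expect_null(cons2$tier2)
})

test_that("growing windows shrink the percent errors to zero at full length", {
  coh <- fixture_cohort(n_units = 4, n_trials = 15, trial_length = 2, seed = 19)
  keep <- vapply(coh$units, unit_inclusion_filter, logical(1))
  units <- coh$units[keep]
  truths <- lapply(seq_along(units), function(u)
    build_ground_truth(units[[u]], n_restarts = 30, seed = 60 + u))
  dw <- dynamic_window_errors(units, truths, c(0.5, 1, 2), n_bootstrap = 100,
                              seed = 2, n_restarts = 15)
  for (m in unique(dw$metric)) {
    d <- dw[dw$metric == m, ]
    expect_lt(d$mean_pct[d$window_s == 2], 0.5)     # full window ~ 0 %
    expect_gt(d$mean_pct[d$window_s == 0.5], d$mean_pct[d$window_s == 2])
    expect_true(all(d$ci_lo <= d$mean_pct & d$mean_pct <= d$ci_hi))
  }
  # a single unit collapses the CI onto the point estimate
  dw1 <- dynamic_window_errors(units[1], truths[1], 2, n_bootstrap = 50, seed = 2,
                               n_restarts = 15)
  expect_equal(dw1$ci_lo, dw1$mean_pct)
  expect_error(dynamic_window_errors(units, truths, 3), "window grid")
})
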