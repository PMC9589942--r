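test_that("pattern enumeration is the documented Cartesian product", {
  pats <- enumerate_patterns()
  expect_equal(nrow(pats), 252)              # 6 x 7 x 6
  expect_equal(nrow(standard_functional_grid()), 300)  # 5 x 5 x 3 x 4
  one <- enumerate_patterns(6, 10, 2)
  expect_equal(nrow(one), 1)
  # points-major ordering, then trials, then length
  small <- enumerate_patterns(c(4, 6), 1, c(1, 2))
  expect_equal(small$n_points, c(4, 4, 6, 6))
  expect_equal(small$trial_length, c(1, 2, 1, 2))
  expect_error(enumerate_patterns(numeric(0), 1, 1), "non-empty")
  expect_error(enumerate_patterns(3, 1, 1), "at least 4")
})

test_that("recording time is the product of the three conditions", {
  expect_equal(recording_time(list(n_points = 6, n_trials = 10, trial_length = 2)), 120)
  expect_equal(recording_time(list(n_points = 6, n_trials = 16, trial_length = 2)), 192)
  expect_equal(recording_time(list(n_points = 4, n_trials = 20, trial_length = 2)), 160)
  expect_equal(recording_time(list(n_points = 1, n_trials = 1, trial_length = 1)), 1)
  # multiplicative and permutation-invariant in its factors
  expect_equal(recording_time(list(n_points = 3, n_trials = 5, trial_length = 7)),
               recording_time(list(n_points = 7, n_trials = 3, trial_length = 5)))
})

test_that("the Monte-Carlo sweep is deterministic and complete", {
  fg <- data.frame(r_max = c(10, 16), c50 = c(40, 60), n = c(2, 3), b = c(1, 2))
  pats <- enumerate_patterns(c(4, 6), c(4, 8), 2)
  mc1 <- run_monte_carlo(fg, pats, scales = c(1, 2), n_replicates = 2,
                         seed = 5, n_restarts = 6)
  mc2 <- run_monte_carlo(fg, pats, scales = c(1, 2), n_replicates = 2,
                         seed = 5, n_restarts = 6)
  expect_identical(as.data.frame(mc1), as.data.frame(mc2))
  expect_equal(nrow(mc1), 2 * 4 * 2 * 2)
  expect_true(all(c("err_rms_points", "err_rms_allpoints", "err_angle_rad") %in% names(mc1)))
  expect_true(all(mc1$ok))
})

test_that("the zero-noise limit drives all errors to zero", {
  fg <- data.frame(r_max = c(10, 32), c50 = c(40, 80), n = c(2, 1), b = c(1, 4))
  pats <- enumerate_patterns(6, 10, 2)
  mc <- run_monte_carlo(fg, pats, scales = c(1, 2, 6), seed = 1,
                        n_restarts = 30, noiseless = TRUE,
                        bounds = fit_bounds(100))
  expect_true(all(mc$ok))
  expect_lt(max(mc$err_rms_points), 1e-3)
  expect_lt(max(mc$err_rms_allpoints), 1e-3)
})

test_that("condition profiles aggregate the sweep as mean with SEM", {
  fg <- data.frame(r_max = 10, c50 = 40, n = 2, b = 1)
  pats <- enumerate_patterns(6, c(2, 10), 2)
  mc <- run_monte_carlo(fg, pats, scales = 1, n_replicates = 4, seed = 3,
                        n_restarts = 6)
  pr <- condition_profiles(mc, "repetitions")
  expect_equal(sort(unique(pr$value)), c(2, 10))
  expect_equal(unique(pr$n), 4)
  expect_true(all(pr$sem >= 0))
  expect_error(condition_profiles(mc, "speed"), "unknown condition")
  # asking for fixed values absent from the sweep is an error
  expect_error(condition_profiles(mc, "length",
                                  fixed = list(n_points = 4, n_trials = 10)),
               "fixed values")
})

test_that("the trade-off point sits where error overtakes log recording time", {
  # forced crossing at the second of two patterns
  tp <- find_tradeoff_point(c(0, 1), c(1000, 10))
  expect_equal(tp$index, 2)
  expect_true(tp$crossed)
  # constructed piecewise-linear curves with a known analytic crossing:
  # normalized error i/10 meets normalized time 1 - i/10 at index 6
  e <- seq(0, 1, length.out = 11)
  times <- 10^seq(3, 1, length.out = 11)
  tp2 <- find_tradeoff_point(e, times)
  expect_equal(tp2$index, 6)
  expect_equal(tp2$time_s, times[6])
  # degenerate flat error: boundary index with a warning flag
  expect_warning(tp3 <- find_tradeoff_point(rep(0, 5), 10^(5:1)), "do not cross")
  expect_false(tp3$crossed)
  expect_equal(tp3$index, 5)
  expect_error(find_tradeoff_point(1, 1), "at least 2")
})
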