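test_that("the theoretical study writes reproducible results and a manifest", {
  out1 <- tempfile(); out2 <- tempfile()
  on.exit(unlink(c(out1, out2), recursive = TRUE))
  cfg <- run_config("theoretical",
                    functional_grid = data.frame(r_max = c(10, 16), c50 = c(40, 60),
                                                 n = c(2, 2), b = c(1, 1)),
                    conditions = list(n_points = c(4, 6), n_trials = c(4, 16),
                                      trial_length = c(1, 2)),
                    scales = c(1, 2), n_replicates = 1, n_restarts = 6,
                    seed = 7, out_dir = out1)
  res <- run_theoretical_study(cfg)
  expect_equal(res$manifest$n_patterns, 8)
  expect_equal(res$manifest$n_functional_combos, 2)
  expect_true(file.exists(file.path(out1, "mc_results.csv")))
  expect_true(file.exists(file.path(out1, "tradeoff.json")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_equal(nrow(res$tradeoff), 2)

  cfg$out_dir <- out2
  res2 <- run_theoretical_study(cfg)
  expect_identical(readLines(file.path(out1, "mc_results.csv")),
                   readLines(file.path(out2, "mc_results.csv")))
  # empty grids fail validation before any compute
  expect_error(run_theoretical_study(run_config("theoretical",
                 functional_grid = data.frame())), "empty")
})

test_that("the validation study produces scores, consensus and windows", {
  coh <- fixture_cohort(n_units = 2, n_trials = 12, trial_length = 2, seed = 23)
  pats <- data.frame(n_points = c(6, 4), n_trials = c(8, 4),
                     trial_length = c(2, 1))
  out <- tempfile(); on.exit(unlink(out, recursive = TRUE))
  cfg <- run_config("validation", cohort = coh, patterns = pats,
                    scales = c(1, 2), n_iterations = 4, n_restarts = 8,
                    ground_truth_restarts = 30,
                    windows = c(1, 2), n_bootstrap = 50,
                    seed = 3, out_dir = out)
  res <- run_validation_study(cfg)
  expect_length(res$included_units, 2)
  expect_true(all(c("mean_rms_points", "mean_rms_allpoints", "mean_angle") %in%
                    names(res$scores)))
  expect_equal(nrow(res$scores), 2 * 2 * 2)  # units x scales x patterns
  expect_true(!is.null(res$consensus$counts))
  expect_equal(sort(unique(res$windows$window_s)), c(1, 2))
  expect_true(file.exists(file.path(out, "pattern_scores.csv")))
  expect_true(file.exists(file.path(out, "consensus.json")))
  expect_true(file.exists(file.path(out, "windows.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$n_units_included, 2)
  expect_equal(sort(unlist(man$recording_times_s)), c(16, 96))
  # rerun reproduces identical rankings
  res2 <- run_validation_study(run_config("validation", cohort = coh,
                    patterns = pats, scales = c(1, 2), n_iterations = 4,
                    n_restarts = 8, ground_truth_restarts = 30, seed = 3))
  expect_equal(res$scores[names(res$scores) != "unit_id"],
               res2$scores[names(res2$scores) != "unit_id"])
})

test_that("a cohort with no responsive unit is an explicit error", {
  spec <- cohort_spec(n_units = 2, n_trials = 4, trial_length = 2, directions = 0,
                      truth_values = list(r_max = 0.5, c50 = 50, n = 2, b = 0.2),
                      seed = 2)
  coh <- generate_cohort(spec)
  cfg <- run_config("validation", cohort = coh,
                    patterns = data.frame(n_points = 4, n_trials = 2,
                                          trial_length = 1))
  expect_error(run_validation_study(cfg), "empty cohort")
})

test_that("consensus patterns carry their recording times through the report", {
  # the four headline patterns span 160-192 s of recording
  pats <- data.frame(n_points = c(6, 6, 4, 4), n_trials = c(16, 30, 12, 20),
                     trial_length = c(2, 1, 4, 2))
  expect_equal(recording_time(pats), c(192, 180, 192, 160))
  expect_equal(range(recording_time(pats)), c(160, 192))
})

test_that("YAML configs parse value grids, including the exponent key", {
  yml <- tempfile(fileext = ".yaml"); on.exit(unlink(yml))
  writeLines(c("study: theoretical",
               "functional_grid:",
               "  r_max: [10, 16]",
               "  c50: [40]",
               "  n: [2, 3]",       # YAML 1.1 would read this key as FALSE
               "  b: [1]",
               "conditions:",
               "  n_points: [4, 6]",
               "  n_trials: [4]",
               "  trial_length: [1]",
               "scales: [1]",
               "n_restarts: 6"), yml)
  cfg <- read_run_config(yml)
  expect_s3_class(cfg$functional_grid, "data.frame")
  expect_equal(sort(names(cfg$functional_grid)), c("b", "c50", "n", "r_max"))
  expect_equal(nrow(cfg$functional_grid), 4)
  res <- run_theoretical_study(cfg)
  expect_equal(nrow(res$mc), 4 * 2 * 1)
  yml2 <- tempfile(fileext = ".yaml"); on.exit(unlink(yml2), add = TRUE)
  writeLines("n_restarts: 6", yml2)
  expect_error(read_run_config(yml2), "study")
})
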