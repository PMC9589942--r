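test_that("Naka-Rushton evaluation satisfies its defining identities", {
  p <- nr_params(r_max = 15, c50 = 20, n = 2, b = 1)
  # c = 0 gives the baseline; c = c50 gives half the dynamic range above it
  expect_equal(evaluate_nre(p, 0), 1)
  expect_equal(evaluate_nre(p, 20), 15 / 2 + 1)
  # hand evaluation at full contrast
  expect_equal(evaluate_nre(p, 100), 15 * 10000 / (10000 + 400) + 1,
               tolerance = 1e-12)
  # the same identities hold across parameter sets
  for (q in list(nr_params(5, 50, 1, 0), nr_params(32, 80, 6, 4),
                 nr_params(0.5, 3, 0.5, 2))) {
    expect_equal(evaluate_nre(q, 0), q$b)
    expect_equal(evaluate_nre(q, q$c50), q$r_max / 2 + q$b)
  }
})

test_that("the curve is non-decreasing and bounded in [b, r_max + b)", {
  grid <- seq(0, 100, by = 0.5)
  set.seed(41)
  for (i in 1:20) {
    q <- nr_params(runif(1, 0.5, 40), runif(1, 5, 95), runif(1, 0.5, 6),
                   runif(1, 0, 5))
    r <- evaluate_nre(q, grid)
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(r >= q$b - 1e-12))
    expect_true(all(r < q$r_max + q$b))
  }
})

test_that("invalid parameters and contrasts are rejected", {
  expect_error(nr_params(-1, 50, 2, 1), "r_max")
  expect_error(nr_params(10, 0, 2, 1), "c50")
  expect_error(nr_params(10, 120, 2, 1), "c50")
  expect_error(nr_params(10, 50, 0, 1), "'n'")
  expect_error(nr_params(10, 50, NaN, 1), "finite")
  p <- fixture_truth()
  expect_error(evaluate_nre(p, -5), "\\[0, 100\\]")
  expect_error(evaluate_nre(p, c(10, NA)), "finite")
})

test_that("bounds derive from the maximal observed response plus 2 SD", {
  pts <- crf_points(c(0, 50, 100), c(2, 10, 20), c(1, 1.5, 2))
  b <- derive_bounds(pts)
  expect_equal(b$r_max_hi, 20 + 2 * 2)
  expect_equal(b$b_hi, b$r_max_hi)     # the baseline shares the ceiling
  expect_equal(b$c50_hi, 100)
  expect_equal(b$n_hi, 6)
  # noiseless single point: MAXERR collapses to zero
  one <- crf_points(50, 7, 0)
  expect_equal(derive_bounds(one)$r_max_hi, 7)
  # the SD at the *maximal-response* contrast is the one that matters
  pts2 <- crf_points(c(0, 50, 100), c(2, 10, 20), c(5, 5, 0.5))
  expect_equal(derive_bounds(pts2)$r_max_hi, 21)
  expect_error(derive_bounds(crf_points(numeric(0), numeric(0))), "empty")
})

test_that("noiseless data are recovered essentially exactly", {
  truth <- fixture_truth()
  fit <- fit_crf(fixture_points(truth), fit_bounds(100), n_restarts = 30, seed = 1)
  rel <- abs(as.double(fit$params) - as.double(truth)) / as.double(truth)
  expect_lt(max(rel), 1e-4)
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-10)
})

test_that("fewer than four contrast points is an error", {
  truth <- fixture_truth()
  pts3 <- crf_points(c(0, 50, 100), evaluate_nre(truth, c(0, 50, 100)))
  expect_error(fit_crf(pts3), "at least 4")
})

test_that("fitted parameters always respect the bounds", {
  set.seed(7)
  for (i in 1:8) {
    pts <- simulate_rates(fixture_truth(), c(0, 10, 30, 50, 70, 100), 1, 2,
                          seed = i)
    b <- derive_bounds(pts)
    f <- fit_crf(pts, b, n_restarts = 10, seed = i)
    expect_lte(f$params$r_max, b$r_max_hi)
    expect_lte(f$params$b, b$b_hi)
    expect_lte(f$params$c50, 100)
    expect_lte(f$params$n, 6)
    expect_gt(f$params$c50, 0)
    expect_gt(f$params$n, 0)
  }
})

test_that("a fixed seed reproduces the fit bit-identically", {
  pts <- simulate_rates(fixture_truth(), c(0, 10, 30, 50, 70, 100), 2, 5,
                        seed = 3)
  f1 <- fit_crf(pts, n_restarts = 15, seed = 42)
  f2 <- fit_crf(pts, n_restarts = 15, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
})

test_that("more repetitions give better parameter recovery", {
  truth <- fixture_truth()
  cc <- c(0, 10, 30, 50, 70, 100)
  err <- function(n_reps, s) {
    pts <- simulate_rates(truth, cc, 2, n_reps, seed = s)
    f <- fit_crf(pts, fit_bounds(100), n_restarts = 10, seed = s + 500)
    angle_error(f, truth)
  }
  seeds <- 1:21
  e64 <- vapply(seeds, function(s) err(64, s), numeric(1))
  e2 <- vapply(seeds, function(s) err(2, s), numeric(1))
  expect_lt(median(e64), median(e2))
})

test_that("CRF points round-trip through CSV and fits serialize to JSON", {
  pts <- crf_points(c(0, 25, 50, 75, 100), c(1, 3, 7, 9, 10), c(0.5, 1, 1, 1, 1.2))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_crf_points(pts, f)
  back <- read_crf_points(f)
  expect_equal(as.data.frame(back), as.data.frame(pts))

  fit <- fit_crf(fixture_points(), fit_bounds(100), n_restarts = 10, seed = 1)
  j <- jsonlite::fromJSON(fit_to_json(fit))
  expect_named(j$params, c("r_max", "c50", "n", "b"))
  expect_equal(j$sse, fit$sse)
  expect_true(is.logical(j$converged))
})
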