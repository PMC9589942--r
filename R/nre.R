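#' Naka-Rushton parameter set
#'
#' Bundles the four parameters of the Naka-Rushton equation
#' \deqn{r(c) = R_{max} \frac{c^n}{c^n + C_{50}^n} + B}
#' which describes the firing rate of a visual neuron as a sigmoidal function
#' of stimulus contrast.
#'
#' @param r_max Dynamic range of the curve, spikes/s (>= 0).
#' @param c50 Half-saturation contrast, percent, in (0, 100].
#' @param n Exponent controlling the steepness of the transition (> 0).
#' @param b Baseline (spontaneous) rate, spikes/s (>= 0).
#' @return An object of class `nr_params`.
#' @examples
#' p <- nr_params(r_max = 15, c50 = 20, n = 2, b = 1)
#' evaluate_nre(p, c(0, 20, 100))
#' @export
nr_params <- function(r_max, c50, n, b) {
  check_number(r_max, "r_max", lo = 0)
  check_number(c50, "c50", lo = 0, hi = 100, lo_open = TRUE)
  check_number(n, "n", lo = 0, lo_open = TRUE)
  check_number(b, "b", lo = 0)
  structure(list(r_max = as.double(r_max), c50 = as.double(c50),
                 n = as.double(n), b = as.double(b)),
            class = "nr_params")
}

#' @export
print.nr_params <- function(x, ...) {
  cat(sprintf("Naka-Rushton parameters: Rmax = %.4g sp/s, C50 = %.4g%%, n = %.4g, B = %.4g sp/s\n",
              x$r_max, x$c50, x$n, x$b))
  invisible(x)
}

#' @export
as.double.nr_params <- function(x, ...) {
  c(r_max = x$r_max, c50 = x$c50, n = x$n, b = x$b)
}

#' Evaluate the Naka-Rushton equation
#'
#' Computes `r(c) = r_max * c^n / (c^n + c50^n) + b` element-wise. The limit
#' at `c = 0` is the baseline `b` (the `c^n` term vanishes for any `n > 0`),
#' so 0% contrast is a legal input even though `c50` itself must be positive.
#'
#' @param params An [nr_params] object.
#' @param contrasts Numeric vector of contrasts in percent, each in \[0, 100\].
#' @return Numeric vector of firing rates in spikes/s, non-decreasing in
#'   contrast and bounded in `[b, r_max + b)`.
#' @export
evaluate_nre <- function(params, contrasts) {
  if (!inherits(params, "nr_params")) params <- do.call(nr_params, as.list(params))
  if (!is.numeric(contrasts) || anyNA(contrasts) || any(!is.finite(contrasts)))
    stop_input("'contrasts' must be finite numbers")
  if (any(contrasts < 0) || any(contrasts > 100))
    stop_input("contrasts must lie in [0, 100] percent")
  cn <- contrasts^params$n
  params$r_max * cn / (cn + params$c50^params$n) + params$b
}

#' Contrast response data points
#'
#' A small tabular container for a measured (or simulated) contrast response
#' function: one row per contrast with the trial-averaged firing rate and,
#' optionally, the across-trial standard deviation of the per-trial rates.
#'
#' @param contrasts Strictly increasing contrasts, percent in \[0, 100\].
#' @param mean_rates Mean firing rate per contrast, spikes/s.
#' @param rate_sds Optional across-trial SD of the rate per contrast, spikes/s.
#' @return A data frame of class `crf_points` with columns `contrast_pct`,
#'   `mean_rate_hz`, `rate_sd_hz`.
#' @export
crf_points <- function(contrasts, mean_rates, rate_sds = NULL) {
  if (length(contrasts) == 0L) stop_input("'contrasts' is empty")
  if (length(mean_rates) != length(contrasts))
    stop_input("'mean_rates' and 'contrasts' lengths differ")
  if (is.unsorted(contrasts, strictly = TRUE))
    stop_input("'contrasts' must be strictly increasing")
  if (is.null(rate_sds)) rate_sds <- rep(NA_real_, length(contrasts))
  if (length(rate_sds) != length(contrasts))
    stop_input("'rate_sds' and 'contrasts' lengths differ")
  structure(data.frame(contrast_pct = as.double(contrasts),
                       mean_rate_hz = as.double(mean_rates),
                       rate_sd_hz = as.double(rate_sds)),
            class = c("crf_points", "data.frame"))
}

#' Fitting bounds for the Naka-Rushton parameters
#'
#' Box constraints used by [fit_crf()]. All lower bounds are 0 (open for
#' `c50` and `n`); the upper bounds on `c50` (100%) and `n` (6) are fixed at
#' values beyond which fitted parameters stop being biologically meaningful.
#'
#' @param r_max_hi Upper bound for `r_max`, spikes/s.
#' @param b_hi Upper bound for the baseline; defaults to `r_max_hi`.
#' @param c50_hi,n_hi Fixed upper bounds; change only for methodological
#'   experiments.
#' @return An object of class `fit_bounds`.
#' @seealso [derive_bounds()] for the data-driven rule.
#' @export
fit_bounds <- function(r_max_hi, b_hi = r_max_hi, c50_hi = 100, n_hi = 6) {
  check_number(r_max_hi, "r_max_hi", lo = 0)
  check_number(b_hi, "b_hi", lo = 0)
  check_number(c50_hi, "c50_hi", lo = 0, lo_open = TRUE)
  check_number(n_hi, "n_hi", lo = 0, lo_open = TRUE)
  structure(list(r_max_hi = as.double(r_max_hi), b_hi = as.double(b_hi),
                 c50_hi = as.double(c50_hi), n_hi = as.double(n_hi)),
            class = "fit_bounds")
}

#' Derive fitting bounds from observed responses
#'
#' The upper bound for `r_max` is `MAX + MAXERR`, where `MAX` is the largest
#' observed mean rate and `MAXERR` is two standard deviations of the
#' per-trial rates at that contrast. The baseline shares the same ceiling.
#' When no SD is available (a single trial, or deterministic rates) `MAXERR`
#' is taken as 0. A silent unit (all rates 0) gets a nominal 1e-3 sp/s
#' ceiling so the search box is never degenerate.
#'
#' @param points A [crf_points] object.
#' @return A [fit_bounds] object.
#' @export
derive_bounds <- function(points) {
  if (!inherits(points, "crf_points")) stop_input("'points' must be a crf_points object")
  if (nrow(points) == 0L) stop_input("'points' is empty")
  i <- which.max(points$mean_rate_hz)
  max_rate <- points$mean_rate_hz[i]
  sd_at_max <- points$rate_sd_hz[i]
  if (is.na(sd_at_max)) sd_at_max <- 0
  hi <- max_rate + 2 * sd_at_max
  if (hi <= 0) hi <- 1e-3
  fit_bounds(r_max_hi = hi)
}

# residuals and analytic Jacobian for the least-squares objective;
# par = (r_max, c50, n, b)
nre_residuals <- function(par, contrasts, rates) {
  cn <- contrasts^par[3]
  par[1] * cn / (cn + par[2]^par[3]) + par[4] - rates
}

nre_jacobian <- function(par, contrasts, rates) {
  r_max <- par[1]; c50 <- par[2]; n <- par[3]
  cn <- contrasts^n
  g <- cn / (cn + c50^n)
  g1g <- g * (1 - g)
  dlog <- log(contrasts) - log(c50)
  dlog[contrasts == 0] <- 0             # g(1-g) already vanishes there
  m <- matrix(1, length(contrasts), 4L)
  m[, 1] <- g                           # d/d r_max
  m[, 2] <- -r_max * g1g * n / c50      # d/d c50
  m[, 3] <- r_max * g1g * dlog          # d/d n
  m                                     # column 4: d/d b = 1
}

#' Fit a contrast response function by bounded multistart least squares
#'
#' Fits the Naka-Rushton equation to mean-rate data points with a bounded
#' trust-region nonlinear least-squares solver ([minpack.lm::nls.lm]),
#' restarted from initial parameter vectors drawn uniformly within the
#' bounds. The restart with the lowest sum of squared errors is kept. A
#' deterministic heuristic start (baseline from the minimum rate, dynamic
#' range from the observed span, half-rise contrast) is always tried first;
#' the multistart loop exits early once a restart reaches an essentially
#' zero residual (`sse_tol`), since no later restart can improve on it.
#'
#' @param points A [crf_points] object with at least 4 contrasts (the model
#'   has 4 free parameters).
#' @param bounds A [fit_bounds] object; defaults to [derive_bounds()] on the
#'   data.
#' @param n_restarts Number of random restarts (default 500).
#' @param seed Optional integer seed making the fit bit-reproducible
#'   regardless of the ambient RNG state.
#' @param max_iter Maximum solver iterations per restart.
#' @param tol Termination tolerance on the objective and the parameters.
#' @param sse_tol Early-exit threshold on the best SSE.
#' @return An object of class `crf_fit`: `params` ([nr_params]), `sse`,
#'   `n_restarts_used`, `converged`, `bounds`.
#' @examples
#' truth <- nr_params(10, 40, 2, 1)
#' cc <- c(0, 5, 10, 20, 40, 60, 80, 100)
#' pts <- crf_points(cc, evaluate_nre(truth, cc))
#' fit_crf(pts, fit_bounds(50), n_restarts = 20, seed = 1)
#' @export
fit_crf <- function(points, bounds = derive_bounds(points), n_restarts = 500,
                    seed = NULL, max_iter = 1000, tol = 1e-11,
                    sse_tol = 1e-12) {
  if (!inherits(points, "crf_points")) stop_input("'points' must be a crf_points object")
  if (nrow(points) < 4L)
    stop_input("too few contrast points: at least 4 are required to fit the 4-parameter model (got ",
               nrow(points), ")")
  if (!inherits(bounds, "fit_bounds")) stop_input("'bounds' must be a fit_bounds object")
  contrasts <- points$contrast_pct
  rates <- points$mean_rate_hz

  eps <- 1e-6  # open lower limits for c50 and n
  lower <- c(0, eps, eps, 0)
  upper <- c(bounds$r_max_hi, bounds$c50_hi, bounds$n_hi, bounds$b_hi)
  upper <- pmax(upper, lower + 1e-9)
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(max_iter, 1024L),
                                     ftol = tol, ptol = tol)

  clip <- function(par) pmin(pmax(par, lower + 1e-9), upper - 1e-9)
  b0 <- min(rates)
  r0 <- max(rates) - b0
  half <- b0 + r0 / 2
  i_half <- which(rates >= half)
  c50_0 <- if (length(i_half) && contrasts[i_half[1]] > 0) contrasts[i_half[1]] else 50
  start0 <- clip(c(max(r0, 1e-3), c50_0, 2, b0))

  local_seed(seed, {
    best <- NULL
    any_conv <- FALSE
    used <- 0L
    for (k in seq_len(n_restarts + 1L)) {
      par0 <- if (k == 1L) start0 else
        clip(stats::runif(4, pmax(lower, eps), upper))
      res <- tryCatch(
        minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                           fn = nre_residuals, jac = nre_jacobian,
                           contrasts = contrasts, rates = rates,
                           control = ctrl),
        error = function(e) NULL)
      used <- used + 1L
      if (is.null(res)) next
      if (res$info %in% 1:3) any_conv <- TRUE
      if (is.null(best) || res$deviance < best$deviance) best <- res
      if (!is.null(best) && best$deviance <= sse_tol) break
    }
    if (is.null(best))
      stop_input("all ", used, " restarts of the least-squares solver failed; ",
                 "check the input rates for degeneracies")
    par <- pmin(pmax(best$par, lower), upper)
    structure(list(params = nr_params(par[1], max(par[2], eps), max(par[3], eps), par[4]),
                   sse = best$deviance,
                   n_restarts_used = used,
                   converged = any_conv,
                   bounds = bounds),
              class = "crf_fit")
  })
}

#' @export
print.crf_fit <- function(x, ...) {
  cat("Naka-Rushton fit (bounded multistart least squares)\n")
  print(x$params)
  cat(sprintf("  SSE = %.6g over %d restart(s); converged: %s\n",
              x$sse, x$n_restarts_used, x$converged))
  invisible(x)
}

#' @export
predict.crf_fit <- function(object, contrasts, ...) {
  evaluate_nre(object$params, contrasts)
}

#' Serialize a fit to JSON
#'
#' @param fit A `crf_fit` object.
#' @param path Optional file path; when omitted, the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "crf_fit"))
  x <- list(params = unclass(fit$params), sse = fit$sse,
            converged = fit$converged, n_restarts_used = fit$n_restarts_used)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Read and write contrast response points as CSV
#'
#' The on-disk format has columns `contrast_pct`, `mean_rate_hz`,
#' `rate_sd_hz`.
#'
#' @param points A [crf_points] object.
#' @param path File path.
#' @return `read_crf_points` returns a [crf_points] object.
#' @export
write_crf_points <- function(points, path) {
  stopifnot(inherits(points, "crf_points"))
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crf_points
#' @export
read_crf_points <- function(path) {
  d <- utils::read.csv(path)
  need <- c("contrast_pct", "mean_rate_hz", "rate_sd_hz")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_input("missing columns in CRF points file: ",
                               paste(miss, collapse = ", "))
  crf_points(d$contrast_pct, d$mean_rate_hz, d$rate_sd_hz)
}
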