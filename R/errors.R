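#' RMS error at selected contrast points
#'
#' Root-mean-square difference between an experimental CRF and a theoretical
#' reference evaluated at the supplied contrasts:
#' \deqn{RMS = \sqrt{\sum_i (E_i - T_i)^2 / N}.}
#' When `contrasts` are the points actually sampled by a pattern this is the
#' discrete estimator (RMS at the sampled points); see [rms_allpoints()] for
#' the dense-grid counterpart.
#'
#' @param experimental The experimental side: a `crf_fit`, an [nr_params]
#'   (fitted curve evaluated at the contrasts), a [crf_points] object (the
#'   raw mean rates at exactly those contrasts), or a plain numeric vector
#'   of responses.
#' @param theoretical The reference: [nr_params] (or `crf_fit`), or a
#'   numeric vector matching `experimental`.
#' @param contrasts Contrasts (percent) at which to compare; required unless
#'   both sides are numeric vectors.
#' @return RMS error in spikes/s.
#' @export
rms_at_points <- function(experimental, theoretical, contrasts = NULL) {
  e <- curve_values(experimental, contrasts, "experimental")
  t_ <- curve_values(theoretical, contrasts, "theoretical")
  if (length(e) != length(t_))
    stop_input("experimental and theoretical values have different lengths")
  if (length(e) == 0L) stop_input("no contrast points to compare")
  sqrt(mean((e - t_)^2))
}

curve_values <- function(x, contrasts, what) {
  if (inherits(x, "crf_fit")) x <- x$params
  if (inherits(x, "nr_params")) {
    if (is.null(contrasts)) stop_input("'contrasts' required to evaluate the ", what, " curve")
    return(evaluate_nre(x, contrasts))
  }
  if (inherits(x, "crf_points")) {
    if (is.null(contrasts)) return(x$mean_rate_hz)
    idx <- match(round(contrasts, 9), round(x$contrast_pct, 9))
    if (anyNA(idx))
      stop_input(what, " points do not contain all requested contrasts")
    return(x$mean_rate_hz[idx])
  }
  if (is.numeric(x)) return(as.double(x))
  stop_input("cannot interpret the ", what, " argument")
}

#' RMS error over the full curve
#'
#' The same RMS statistic as [rms_at_points()], but computed on a dense grid
#' of `n_grid` contrasts spanning 0 to 100% (default 100), comparing the two
#' parameterized curves continuously rather than at the sampled points only.
#'
#' @param experimental_fit,theoretical [nr_params] or `crf_fit` objects.
#' @param n_grid Number of grid contrasts (>= 2).
#' @return RMS error in spikes/s.
#' @export
rms_allpoints <- function(experimental_fit, theoretical, n_grid = 100) {
  check_number(n_grid, "n_grid", lo = 2)
  grid <- seq(0, 100, length.out = n_grid)
  rms_at_points(experimental_fit, theoretical, grid)
}

#' Angle between two Naka-Rushton parameter vectors
#'
#' Arranges each parameter set as the 4-vector `[Rmax, B, C50, n]` (raw
#' units: spikes/s, spikes/s, percent, dimensionless) and returns the angle
#' \deqn{\sigma = \arccos\left(\frac{\sigma_E \cdot \sigma_T}{|\sigma_E||\sigma_T|}\right)}
#' in radians. Small angles mean similar parameters; the measure is
#' invariant to a positive rescaling of either vector. No unit
#' harmonization is applied.
#'
#' @param sigma_e,sigma_t [nr_params] objects (or numeric 4-vectors already
#'   in `[Rmax, B, C50, n]` order).
#' @return Angle in radians, clamped to \[0, pi\].
#' @export
angle_error <- function(sigma_e, sigma_t) {
  ve <- angle_vector(sigma_e)
  vt <- angle_vector(sigma_t)
  ne <- sqrt(sum(ve^2)); nt <- sqrt(sum(vt^2))
  if (ne == 0 || nt == 0) stop_input("zero-length parameter vector")
  acos(min(1, max(-1, sum(ve * vt) / (ne * nt))))
}

angle_vector <- function(x) {
  if (inherits(x, "crf_fit")) x <- x$params
  if (inherits(x, "nr_params")) return(c(x$r_max, x$b, x$c50, x$n))
  if (is.numeric(x) && length(x) == 4L) return(as.double(x))
  stop_input("expected nr_params or a numeric 4-vector [Rmax, B, C50, n]")
}

#' Express an error as a percentage of a reference scale
#'
#' Used by the growing-window analysis to put the three error estimators on
#' a common percent scale. The conventional references are the mean
#' theoretical response over the curve for the RMS errors (see
#' [mean_response()]) and `pi/2` for the angle; both are plain arguments, so
#' other normalizations can be substituted.
#'
#' @param error_value Error value (>= 0).
#' @param reference_scale Positive reference on the same scale as the error.
#' @return `100 * error_value / reference_scale`.
#' @export
percent_variation <- function(error_value, reference_scale) {
  if (!is.numeric(reference_scale) || any(reference_scale <= 0))
    stop_input("'reference_scale' must be positive")
  100 * error_value / reference_scale
}

#' Mean response of a Naka-Rushton curve over the contrast range
#'
#' @param params An [nr_params] object.
#' @param n_grid Grid resolution (default 100).
#' @return Mean of the curve over `n_grid` contrasts spanning 0 to 100%.
#' @export
mean_response <- function(params, n_grid = 100) {
  mean(evaluate_nre(params, seq(0, 100, length.out = n_grid)))
}

#' Compute the three fit-error estimators at once
#'
#' @param fit Experimental `crf_fit` or [nr_params].
#' @param truth Reference [nr_params].
#' @param contrasts Sampled contrasts for the discrete RMS.
#' @param n_grid Grid size for the full-curve RMS.
#' @return Named numeric vector `rms_points`, `rms_allpoints`, `angle_rad`.
#' @export
error_triple <- function(fit, truth, contrasts, n_grid = 100) {
  c(rms_points = rms_at_points(fit, truth, contrasts),
    rms_allpoints = rms_allpoints(fit, truth, n_grid),
    angle_rad = angle_error(fit, truth))
}
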