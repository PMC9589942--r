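#' The ten contrast-spacing scales
#'
#' Each scale is a rule that places a requested number of contrast values on
#' \[0, 100\]%. Linear scales space a fraction range evenly; logarithmic
#' scales place points between decades `10^a` and `10^b` and weight by 100
#' to obtain percentages. Every scale except scale 6 contains an explicit
#' point at 0% contrast (the blank condition from which the baseline is
#' estimated); scale 6 is the log spacing without it, and scale 3 is the
#' only scale whose largest contrast falls short of 100%.
#'
#' @return A data frame with one row per scale: `scale_id`, `kind`,
#'   `lower`, `upper`, `includes_zero`, `description`.
#' @export
scale_table <- function() {
  data.frame(
    scale_id = 1:10,
    kind = c("linear", "logarithmic", "logarithmic", "logarithmic",
             "logarithmic", "logarithmic", "logarithmic", "linear",
             "linear", "logarithmic"),
    lower = c(0.0, -1.2, -1.0, -0.3, -0.7, -0.5, -0.5, 0.1, 0.25, -0.7),
    upper = c(1.0,  0.0, -0.15, 0.0,  0.0,  0.0, -0.15, 0.9, 0.75, -0.1),
    includes_zero = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    description = c("linearly spaced",
                    "log, concentrated around 0",
                    "log, concentrated around 0.25 (lacks 100%)",
                    "log, concentrated around 1",
                    "log, concentrated around 0.75",
                    "log spacing without the 0% point",
                    "log, concentrated around 0.5",
                    "linear counterpart of 7 (towards the borders)",
                    "linear, less spread than 8",
                    "log-concentrated around 0.5"),
    stringsAsFactors = FALSE
  )
}

#' Generate contrasts for one scale
#'
#' For scales that include 0% contrast the first point is exactly 0 and the
#' remaining `n_points - 1` points follow the scale's spacing between its
#' bounds (for scale 1 the natural first point already is 0, so the full
#' spacing uses all `n_points`). Scale 6 draws all `n_points` from its log
#' spacing and therefore has a strictly positive minimum.
#'
#' @param scale_id Integer 1..10, see [scale_table()].
#' @param n_points Number of contrasts to generate (>= 4).
#' @return Strictly increasing numeric vector of length `n_points`,
#'   contrasts in percent within \[0, 100\].
#' @examples
#' generate_scale(1, 6)  # 0 20 40 60 80 100
#' generate_scale(2, 6)  # 0 and five log-spaced points up to 100
#' @export
generate_scale <- function(scale_id, n_points) {
  tab <- scale_table()
  if (!is.numeric(scale_id) || length(scale_id) != 1L || !(scale_id %in% tab$scale_id))
    stop_input("unknown scale_id: ", format(scale_id))
  check_number(n_points, "n_points", lo = 4)
  row <- tab[tab$scale_id == scale_id, ]
  span <- function(m) {
    if (row$kind == "linear") 100 * seq(row$lower, row$upper, length.out = m)
    else 100 * 10^seq(row$lower, row$upper, length.out = m)
  }
  vals <- if (!row$includes_zero) {
    span(n_points)
  } else if (row$kind == "linear" && row$lower == 0) {
    span(n_points)
  } else {
    c(0, span(n_points - 1L))
  }
  if (is.unsorted(vals, strictly = TRUE))
    stop_input("internal error: scale ", scale_id, " is not strictly increasing")
  vals
}

#' Map scale contrasts onto an available contrast list
#'
#' Replaces each requested contrast by its nearest neighbour in the list of
#' contrasts actually measured (ties broken towards the lower contrast).
#' Collisions are resolved greedily so the requested count is preserved:
#' each requested contrast, in increasing order, takes the nearest value
#' not already used.
#'
#' @param scale_contrasts Contrasts requested by a scale, percent.
#' @param available Sorted vector of measured contrasts, percent.
#' @return Sorted vector of `length(scale_contrasts)` distinct values drawn
#'   from `available`.
#' @export
map_to_available <- function(scale_contrasts, available) {
  if (length(available) == 0L) stop_input("'available' is empty")
  if (is.unsorted(available, strictly = TRUE))
    stop_input("'available' must be sorted and free of duplicates")
  if (length(scale_contrasts) > length(available))
    stop_input("requested ", length(scale_contrasts),
               " contrasts but only ", length(available), " are available")
  used <- logical(length(available))
  out <- numeric(length(scale_contrasts))
  for (i in seq_along(scale_contrasts)) {
    d <- abs(available - scale_contrasts[i])
    d[used] <- Inf
    j <- which.min(d)  # ties resolve to the first (lower) value
    used[j] <- TRUE
    out[i] <- available[j]
  }
  sort(out)
}
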