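# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a root seed
#'
#' All stochastic operations in the package draw their randomness from named
#' sub-streams of one root seed, so that partial reruns (a single unit, a
#' single replicate) are stable. The mixing keeps every derived seed inside
#' the 32-bit integer range that `set.seed()` accepts.
#'
#' @param seed Root integer seed.
#' @param ... Integer indices identifying the sub-stream (unit, replicate, ...).
#' @return A single integer seed.
#' @export
mix_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483587
  for (k in seq_along(idx)) {
    # affine step mod a prime < 2^31; doubles stay exact (< 2^53)
    s <- (s * 69069 + (as.double(idx[k]) %% 100000) * 7919 + 12345) %% 2147483587
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. With seed = NULL the expression runs against
# the ambient RNG stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf, lo_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("'%s' must be a single finite number", name))
  if (x < lo || x > hi || (lo_open && x == lo))
    stop_input(sprintf("'%s' = %g is outside its allowed range %s%g, %g]",
                       name, x, if (lo_open) "(" else "[", lo, hi))
  invisible(x)
}
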