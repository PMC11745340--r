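#' @keywords internal
"_PACKAGE"

# Canonical ordering of the five scored sleep stages used throughout.
STAGES <- c("N1", "N2", "N3", "REM", "Wake")

#' Wrap angles to (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; the convention here is (-pi, pi]
  out[out == -pi] <- pi
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Linear interpolation of the lag at which `y` crosses `level` between
# consecutive grid points i and i+1.
interp_crossing <- function(x, y, i, level) {
  x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}
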