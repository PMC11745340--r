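# Cardinal-spline history basis. The history term of the log intensity is
# sum_k h_k g_k(lag), where the g_k are cardinal (Catmull-Rom-type)
# interpolation basis functions over a fixed knot sequence of lags: the
# spline through control values {h_k} passes exactly through (knot_k, h_k).
# Outside the knot span the basis is identically 0, so the multiplicative
# history modulation exp(sum h_k g_k) returns to 1 at long lags.

# Default knot layouts: dense where short-term structure (refractoriness,
# rebound excitation) lives, sparse at long lags out to the infraslow range.
KNOTS_SHORT <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15)
KNOTS_LONG <- c(KNOTS_SHORT, 20, 30, 40, 50, 60, 75, 90)

#' Cardinal-spline history basis
#'
#' @param knots strictly increasing lag positions in seconds; first >= 0,
#'   last <= 90; at least 4 knots.
#' @param tension cardinal-spline tension parameter; 0.5 gives the
#'   Catmull-Rom spline.
#' @return an object of class `history_basis` with fields `knots`, `K`,
#'   `tension`, `max_lag_s`.
#' @export
history_basis <- function(knots = KNOTS_SHORT, tension = 0.5) {
  knots <- as.numeric(knots)
  if (length(knots) < 4) stop_validation("need at least 4 knots")
  if (is.unsorted(knots, strictly = TRUE))
    stop_validation("knots must be strictly increasing")
  if (knots[1] < 0 || knots[length(knots)] > 90)
    stop_validation("knots must lie within [0, 90] s")
  structure(list(knots = knots, K = length(knots), tension = tension,
                 max_lag_s = knots[length(knots)]),
            class = "history_basis")
}

#' @export
print.history_basis <- function(x, ...) {
  cat(sprintf("<history_basis> K = %d cardinal-spline functions on [%.3g, %.3g] s (tension %.2g)\n",
              x$K, x$knots[1], x$max_lag_s, x$tension))
  invisible(x)
}

#' Evaluate the history basis at a set of lags
#'
#' Returns the matrix `B` with `B[i, k] = g_k(lag_i)`, so the spline through
#' control values `h` is `B %*% h`. Within each knot interval the value is the
#' cubic Hermite blend of the two surrounding control values with cardinal
#' tangents `m_i = 2 * tension * (h[i+1] - h[i-1]) / (x[i+1] - x[i-1])`
#' (one-sided at the ends). Lags outside the knot span evaluate to 0 in every
#' column; interpolation weights at any interior lag sum to 1.
#'
#' @param basis a [history_basis()].
#' @param lags numeric vector of lags in seconds.
#' @return numeric matrix, `length(lags)` by `basis$K`.
#' @export
eval_history_basis <- function(basis, lags) {
  stopifnot(inherits(basis, "history_basis"))
  x <- basis$knots
  K <- basis$K
  n <- length(lags)
  B <- matrix(0, n, K)
  inside <- which(lags >= x[1] & lags <= x[K])
  if (!length(inside)) return(B)
  t_in <- lags[inside]
  seg <- findInterval(t_in, x, rightmost.closed = TRUE)
  seg <- pmin(seg, K - 1L)
  d <- x[seg + 1L] - x[seg]
  u <- (t_in - x[seg]) / d
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  add <- function(rows, cols, val) {
    ok <- cols >= 1L & cols <= K
    idx <- cbind(rows[ok], cols[ok])
    B[idx] <<- B[idx] + val[ok]
  }
  add(inside, seg, h00)
  add(inside, seg + 1L, h01)
  # tangent at the left knot of each segment
  tangent_weights <- function(i) {
    # m_i = 2c (y_{i+1} - y_{i-1}) / (x_{i+1} - x_{i-1}) interior;
    # one-sided difference at the boundary knots
    lo <- ifelse(i == 1L, 1L, i - 1L)
    hi <- ifelse(i == K, K, i + 1L)
    list(lo = lo, hi = hi, w = 2 * basis$tension / (x[hi] - x[lo]))
  }
  tw <- tangent_weights(seg)
  add(inside, tw$hi, h10 * d * tw$w)
  add(inside, tw$lo, -h10 * d * tw$w)
  tw <- tangent_weights(seg + 1L)
  add(inside, tw$hi, h11 * d * tw$w)
  add(inside, tw$lo, -h11 * d * tw$w)
  B
}

#' Evaluate the history spline at given lags
#'
#' Convenience wrapper: the log history modulation `sum_k h_k g_k(lag)` for
#' control values `h`.
#'
#' @param basis a [history_basis()].
#' @param h control values, one per knot.
#' @param lags numeric vector of lags in seconds.
#' @return numeric vector of log modulation values.
#' @export
eval_history_spline <- function(basis, h, lags) {
  drop(eval_history_basis(basis, lags) %*% h)
}
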