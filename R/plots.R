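# Base-graphics plot methods for the main read-outs.

#' Plot a history modulation curve
#'
#' Solid curve with shaded pointwise 95% CI and a reference line at 1
#' (no modulation).
#'
#' @param x a `history_curve`.
#' @param truth optional second curve (e.g. [true_history_curve()]) overlaid
#'   as a dashed line.
#' @param main,xlab,ylab usual graphics labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.history_curve <- function(x, truth = NULL, main = "History modulation",
                               xlab = "Lag since last spindle (s)",
                               ylab = "Multiplicative effect on rate", ...) {
  ylim <- range(0, x$ci_high, if (!is.null(truth)) truth$modulation, na.rm = TRUE)
  graphics::plot(x$lag, x$modulation, type = "n", ylim = ylim,
                 main = main, xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$lag, rev(x$lag)), c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::abline(h = 1, lty = 3)
  graphics::lines(x$lag, x$modulation, lwd = 2)
  if (!is.null(truth))
    graphics::lines(truth$lag, truth$modulation, lty = 2, col = "red3")
  invisible(x)
}

#' Plot preferred phase versus sleep depth
#'
#' @param x a `phase_depth_curve`.
#' @param main,xlab,ylab usual graphics labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phase_depth_curve <- function(x, main = "Preferred phase vs sleep depth",
                                   xlab = "Normalized SO power",
                                   ylab = "Preferred phase (rad)", ...) {
  graphics::plot(x$sop, x$phi_pref, type = "n",
                 ylim = range(x$ci_low, x$ci_high), main = main,
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$sop, rev(x$sop)), c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::abline(h = 0, lty = 3)
  graphics::lines(x$sop, x$phi_pref, lwd = 2)
  invisible(x)
}

#' Polar summary of a phase-coupling estimate
#'
#' Draws the preferred-phase direction (arrow length = coupling magnitude)
#' with its CI arc on a unit circle; phase 0 (SO peak) points right.
#'
#' @param x a `phase_coupling`.
#' @param ... unused.
#' @export
plot.phase_coupling <- function(x, ...) {
  graphics::plot(0, 0, type = "n", xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Preferred phase (%s)", x$context))
  th <- seq(-pi, pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey60")
  graphics::text(c(1.12, -1.12, 0, 0), c(0, 0, 1.12, -1.12),
                 c("0 (peak)", expression(pi), expression(pi / 2),
                   expression(-pi / 2)), cex = 0.8)
  r <- min(x$magnitude, 1)
  graphics::arrows(0, 0, r * cos(x$phi_pref), r * sin(x$phi_pref),
                   lwd = 2, length = 0.1)
  if (x$has_preferred_phase) {
    arc <- seq(x$phi_pref - x$ci_halfwidth, x$phi_pref + x$ci_halfwidth,
               length.out = 60)
    graphics::lines(1.05 * cos(arc), 1.05 * sin(arc), lwd = 3, col = "red3")
  }
  invisible(x)
}
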