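# Scientific read-outs of a fitted model: the history modulation curve and
# its features, the infraslow multiplier, and SO-phase coupling across
# stages and the sleep-depth (SOP) continuum.

#' History modulation curve
#'
#' The multiplicative effect of a previous spindle on the current rate as a
#' function of the lag since that spindle: `exp(sum_k h_k g_k(lag))`, with a
#' pointwise 95% CI obtained on the log scale from the covariance of the
#' history coefficients (`exp(linear +/- 1.96 SE)`).
#'
#' @param model fitted `spindle_ppglm` with a history term.
#' @param lag_grid lags (s) at which to evaluate; defaults to a 0.05-s grid
#'   over the basis span.
#' @return data.frame of class `history_curve` with columns `lag`,
#'   `modulation`, `ci_low`, `ci_high`.
#' @export
history_modulation_curve <- function(model, lag_grid = NULL) {
  stopifnot(inherits(model, "spindle_ppglm"))
  if (is.null(model$basis))
    stop_validation("model has no history term")
  if (is.null(lag_grid))
    lag_grid <- seq(0, model$basis$max_lag_s, by = 0.05)
  if (min(lag_grid) < 0 || max(lag_grid) > 90)
    stop_validation("lag_grid must lie within [0, 90] s")
  cols <- model$term_groups$history
  h <- model$coefficients[cols]
  B <- eval_history_basis(model$basis, lag_grid)
  f <- drop(B %*% h)
  V <- vcov_block(model, cols)
  se <- sqrt(pmax(rowSums((B %*% V) * B), 0))
  out <- data.frame(lag = lag_grid, modulation = exp(f),
                    ci_low = exp(f - 1.96 * se), ci_high = exp(f + 1.96 * se))
  class(out) <- c("history_curve", "data.frame")
  out
}

#' Summary features of a history modulation curve
#'
#' The refractory period is the length of the maximal contiguous run starting
#' at lag 0 over which the upper CI stays below 1; the excitatory period is
#' the length of the longest contiguous run anywhere in the curve with the
#' lower CI above 1; peak height/time are the modulation maximum inside that
#' run. CI crossings of 1 are located by linear interpolation between grid
#' points. Empty windows give 0 for the refractory/excitatory lengths and
#' NaN for the peak.
#'
#' @param curve a [history_modulation_curve()] result (or any data.frame with
#'   `lag`, `modulation`, `ci_low`, `ci_high`).
#' @return list of class `history_features`: `refractory_s`, `excitatory_s`,
#'   `peak_time_s`, `peak_height`, and (when the curve spans 70 s)
#'   `infraslow_multiplier`.
#' @export
extract_history_features <- function(curve) {
  lag <- curve$lag
  hi <- curve$ci_high
  lo <- curve$ci_low
  mod <- curve$modulation

  # refractory: anchored at lag 0; first upward crossing of 1 by the upper CI
  if (hi[1] >= 1) {
    refractory <- 0
  } else {
    i <- which(hi >= 1)[1]
    refractory <- if (is.na(i)) lag[length(lag)] - lag[1]
                  else interp_crossing(lag, hi, i - 1L, 1) - lag[1]
  }

  # excitatory: longest contiguous run with lower CI > 1, boundaries
  # interpolated; peak searched inside that run
  sig <- lo > 1
  excitatory <- 0
  peak_time <- NaN
  peak_height <- NaN
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    lens <- numeric(length(runs))
    bounds <- matrix(0, length(runs), 2)
    for (j in seq_along(runs)) {
      a <- starts[runs[j]]
      b <- ends[runs[j]]
      left <- if (a == 1L) lag[1] else interp_crossing(lag, lo, a - 1L, 1)
      right <- if (b == length(lag)) lag[b] else interp_crossing(lag, lo, b, 1)
      lens[j] <- right - left
      bounds[j, ] <- c(a, b)
    }
    best <- which.max(lens)
    excitatory <- lens[best]
    seg <- bounds[best, 1]:bounds[best, 2]
    peak_height <- max(mod[seg])
    peak_time <- lag[seg[which.max(mod[seg])]]
  }

  out <- list(refractory_s = refractory, excitatory_s = excitatory,
              peak_time_s = peak_time, peak_height = peak_height,
              infraslow_multiplier = if (max(lag) >= 70)
                infraslow_multiplier(curve) else NA_real_)
  class(out) <- "history_features"
  out
}

#' @export
print.history_features <- function(x, ...) {
  cat(sprintf(paste0("<history_features> refractory %.2f s | excitatory %.2f s | ",
                     "peak %.2f at %.2f s | infraslow multiplier %s\n"),
              x$refractory_s, x$excitatory_s, x$peak_height, x$peak_time_s,
              if (is.na(x$infraslow_multiplier)) "n/a"
              else sprintf("%.3f", x$infraslow_multiplier)))
  invisible(x)
}

#' Infraslow multiplier of a long-range history curve
#'
#' Mean modulation over the infraslow window, computed as the trapezoidal
#' area of the modulation over 40-70 s divided by the 30-s window, so a null
#' (flat at 1) curve yields exactly 1.
#'
#' @param curve a history curve spanning at least 70 s of lag.
#' @param window numeric length-2, the lag window in seconds (default
#'   `c(40, 70)`).
#' @return scalar mean modulation over the window.
#' @export
infraslow_multiplier <- function(curve, window = c(40, 70)) {
  if (max(curve$lag) < window[2] || min(curve$lag) > window[1])
    stop_validation("curve must span the %g-%g s window", window[1], window[2])
  grid <- sort(unique(c(window, curve$lag[curve$lag >= window[1] &
                                          curve$lag <= window[2]])))
  m <- stats::approx(curve$lag, curve$modulation, grid)$y
  sum(diff(grid) * (utils::head(m, -1) + utils::tail(m, -1)) / 2) / diff(window)
}

# Effective phase coefficient pair and its covariance for a given context.
effective_phase_pair <- function(model, context = NULL, sop_level = NULL) {
  if (is.null(model$term_groups$phase))
    stop_validation("model has no SO-phase term")
  cols <- model$term_groups$phase
  w <- stats::setNames(numeric(length(model$coefficients)),
                       names(model$coefficients))
  wc <- w; wc[cols[1]] <- 1
  ws <- w; ws[cols[2]] <- 1
  if (!is.null(context)) {
    if (is.null(model$term_groups$stage_phase))
      stop_validation("stage-specific phase requires a stage-phase interaction term")
    if (!context %in% STAGES)
      stop_validation("unknown stage '%s'", context)
    wc[paste0("stagephase_", context, "_cos")] <- 1
    ws[paste0("stagephase_", context, "_sin")] <- 1
  }
  if (!is.null(sop_level)) {
    if (is.null(model$term_groups$sop_phase))
      stop_validation("SOP-dependent phase requires a SOP-phase interaction term")
    wc["sopphase_cos"] <- sop_level
    ws["sopphase_sin"] <- sop_level
  }
  all_cols <- names(model$coefficients)
  V <- vcov_block(model, all_cols)
  b <- c(sum(wc * model$coefficients), sum(ws * model$coefficients))
  W <- rbind(wc, ws)
  list(b = b, V = W %*% V %*% t(W))
}

phase_ci_halfwidth <- function(b, V) {
  M2 <- sum(b^2)
  if (M2 == 0) return(Inf)
  gr <- c(-b[2], b[1]) / M2
  se <- sqrt(max(drop(t(gr) %*% V %*% gr), 0))
  1.96 * se
}

#' SO-phase tuning of the fitted intensity
#'
#' The phase contribution `b1 cos(phi) + b2 sin(phi)` is mathematically
#' equivalent to `M cos(phi - phi_pref)` with coupling magnitude
#' `M = sqrt(b1^2 + b2^2)` and preferred phase `phi_pref = atan2(b2, b1)`.
#' For a stage context the effective pair adds the stage's interaction
#' coefficients to the global pair. The CI on the preferred phase comes from
#' the delta method on the angle; an arc of width >= 2 pi is reported as "no
#' statistically relevant preferred phase".
#'
#' @param model fitted `spindle_ppglm` including a phase term.
#' @param context optional stage label (`"N1"`..`"Wake"`) for stage-specific
#'   coupling; NULL for the global pair.
#' @return list of class `phase_coupling`: `magnitude`, `phi_pref`, `ci`
#'   (two wrapped angles), `ci_halfwidth`, `has_preferred_phase`, `context`.
#' @export
phase_tuning <- function(model, context = NULL) {
  ep <- effective_phase_pair(model, context = context)
  M <- sqrt(sum(ep$b^2))
  phi <- atan2(ep$b[2], ep$b[1])
  hw <- phase_ci_halfwidth(ep$b, ep$V)
  structure(
    list(magnitude = M, phi_pref = phi,
         ci = wrap_angle(c(phi - hw, phi + hw)), ci_halfwidth = hw,
         has_preferred_phase = is.finite(hw) && 2 * hw < 2 * pi,
         context = if (is.null(context)) "global" else context),
    class = "phase_coupling")
}

#' @export
print.phase_coupling <- function(x, ...) {
  cat(sprintf("<phase_coupling> %s: M = %.3f, phi_pref = %.3f rad %s\n",
              x$context, x$magnitude, x$phi_pref,
              if (x$has_preferred_phase)
                sprintf("(95%% CI half-width %.3f rad)", x$ci_halfwidth)
              else "(no statistically relevant preferred phase)"))
  invisible(x)
}

#' Preferred phase as a function of sleep depth (SOP)
#'
#' For a model with SOP-phase interaction terms, the effective phase pair at
#' SOP level `u` is `(beta1 + gamma1 u, beta2 + gamma2 u)`; the preferred
#' phase and its delta-method CI are evaluated on a grid of SOP levels. The
#' curve is unwrapped along the grid before CI construction so a drift across
#' the +/-pi seam stays continuous, then re-wrapped for reporting.
#'
#' @param model fitted `spindle_ppglm` with a SOP-phase block.
#' @param sop_grid SOP levels in `[0, 1]`.
#' @return data.frame of class `phase_depth_curve` with columns `sop`,
#'   `phi_pref`, `ci_low`, `ci_high`, `magnitude` (`phi_pref` wrapped;
#'   `ci_*` on the unwrapped scale centered at `phi_pref`).
#' @export
preferred_phase_vs_depth <- function(model, sop_grid = seq(0, 1, by = 0.05)) {
  if (is.null(model$term_groups$sop_phase))
    stop_validation("model has no SOP-phase interaction block")
  if (min(sop_grid) < 0 || max(sop_grid) > 1)
    stop_validation("sop_grid must lie within [0, 1]")
  res <- lapply(sop_grid, function(u) {
    ep <- effective_phase_pair(model, sop_level = u)
    c(phi = atan2(ep$b[2], ep$b[1]), M = sqrt(sum(ep$b^2)),
      hw = phase_ci_halfwidth(ep$b, ep$V))
  })
  phi <- vapply(res, `[[`, numeric(1), "phi")
  # unwrap along the grid to avoid seam jumps
  dphi <- c(0, wrap_angle(diff(phi)))
  phi_u <- phi[1] + cumsum(dphi)
  hw <- vapply(res, `[[`, numeric(1), "hw")
  out <- data.frame(sop = sop_grid, phi_pref = wrap_angle(phi_u),
                    ci_low = phi_u - hw, ci_high = phi_u + hw,
                    magnitude = vapply(res, `[[`, numeric(1), "M"))
  class(out) <- c("phase_depth_curve", "data.frame")
  out
}
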