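#' Spindle event train
#'
#' An ordered set of spindle event times (seconds from recording start)
#' together with the recording duration. Events are single time points, one
#' per detected spindle.
#'
#' @param times numeric vector of event times in seconds, strictly increasing,
#'   all within `[0, duration_s]`.
#' @param duration_s recording length in seconds (> 0).
#' @param subject_id optional subject label.
#' @return an object of class `event_train`.
#' @export
event_train <- function(times, duration_s, subject_id = "subject") {
  times <- as.numeric(times)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop_validation("duration_s must be a single positive number")
  if (anyNA(times)) stop_validation("event times contain NA")
  if (length(times) && (min(times) < 0 || max(times) > duration_s))
    stop_validation("event times must lie in [0, duration_s]")
  if (is.unsorted(times, strictly = TRUE))
    stop_validation("event times must be strictly increasing (no duplicates)")
  structure(
    list(times = times, duration_s = as.numeric(duration_s),
         subject_id = as.character(subject_id)),
    class = "event_train"
  )
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %s: %d events over %.1f s (%.2f events/min)\n",
              x$subject_id, length(x$times), x$duration_s,
              60 * length(x$times) / x$duration_s))
  invisible(x)
}

#' Hypnogram
#'
#' Scored sleep stages on fixed-length epochs (conventionally 30 s). Only the
#' five standard labels N1, N2, N3, REM, Wake are accepted.
#'
#' @param stages character vector of per-epoch stage labels.
#' @param epoch_s epoch length in seconds (default 30).
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad))
    stop_validation("invalid stage label(s): %s (allowed: %s)",
                    paste(bad, collapse = ", "), paste(STAGES, collapse = ", "))
  if (!length(stages)) stop_validation("hypnogram must have at least one epoch")
  if (!is.numeric(epoch_s) || epoch_s <= 0)
    stop_validation("epoch_s must be positive")
  structure(list(stages = stages, epoch_s = as.numeric(epoch_s)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat(sprintf("<hypnogram> %d x %.0f-s epochs (%.1f h)\n",
              length(x$stages), x$epoch_s,
              length(x$stages) * x$epoch_s / 3600))
  print(tab)
  invisible(x)
}

hypnogram_duration <- function(hyp) length(hyp$stages) * hyp$epoch_s

#' Stage label at arbitrary times
#'
#' Looks up the hypnogram stage for each time (half-open epochs
#' `[k*epoch, (k+1)*epoch)`; times beyond the last epoch map to it).
#'
#' @param hyp a [hypnogram()].
#' @param t numeric vector of times in seconds.
#' @return character vector of stage labels.
#' @export
stage_at <- function(hyp, t) {
  idx <- pmin(floor(t / hyp$epoch_s) + 1L, length(hyp$stages))
  hyp$stages[pmax(idx, 1L)]
}

#' Bin an event train into per-bin counts
#'
#' Counts events in half-open bins `[k*dt, (k+1)*dt)`. The discrete-time
#' likelihood treats bins as Bernoulli trials, so counts are capped at 1; any
#' collision (two events in one bin) is reported via a warning and the
#' `collisions` attribute.
#'
#' @param train an [event_train()].
#' @param dt_s bin width in seconds.
#' @return integer vector of 0/1 counts of length `ceiling(duration/dt)`, with
#'   attribute `collisions` giving the number of capped events.
#' @export
bin_events <- function(train, dt_s) {
  stopifnot(inherits(train, "event_train"))
  if (!is.numeric(dt_s) || dt_s <= 0) stop_validation("dt_s must be positive")
  n_bins <- ceiling(train$duration_s / dt_s)
  counts <- integer(n_bins)
  if (length(train$times)) {
    idx <- pmin(floor(train$times / dt_s) + 1L, n_bins)
    tab <- tabulate(idx, nbins = n_bins)
    collisions <- sum(pmax(tab - 1L, 0L))
    if (collisions > 0)
      warning(sprintf("%d event(s) collided within a %.3g-s bin; counts capped at 1",
                      collisions, dt_s))
    counts <- pmin(tab, 1L)
  } else {
    collisions <- 0L
  }
  attr(counts, "collisions") <- collisions
  counts
}

#' Covariate series on the model time grid
#'
#' Aligns per-bin sleep stage, SO phase, normalized SO power and binary event
#' counts on a common grid of width `dt_s`. This is the container the design
#' matrix is built from.
#'
#' @param dt_s bin width in seconds.
#' @param stage character vector of per-bin stage labels.
#' @param phase per-bin SO phase in (-pi, pi] (0 = SO peak / up-state).
#' @param sop per-bin normalized SO power in `[0, 1]` (may be NULL if the
#'   model never uses SO power).
#' @param counts per-bin 0/1 event counts.
#' @return an object of class `covariate_series` with elements `dt_s`, `time`
#'   (bin centers), `stage`, `phase`, `sop`, `counts`.
#' @export
covariate_series <- function(dt_s, stage, phase, sop = NULL, counts) {
  n <- length(stage)
  if (length(phase) != n || length(counts) != n ||
      (!is.null(sop) && length(sop) != n))
    stop_validation("stage, phase, sop and counts must have equal length")
  bad <- setdiff(unique(stage), STAGES)
  if (length(bad))
    stop_validation("invalid stage label(s): %s", paste(bad, collapse = ", "))
  if (any(!is.finite(phase)) || any(phase <= -pi - 1e-9) || any(phase > pi + 1e-9))
    stop_validation("phase must be finite and wrapped to (-pi, pi]")
  if (!is.null(sop) && (any(!is.finite(sop)) || min(sop) < -1e-9 || max(sop) > 1 + 1e-9))
    stop_validation("sop must lie in [0, 1]")
  if (!all(counts %in% c(0L, 1L)))
    stop_validation("counts must be binary (0/1)")
  structure(
    list(dt_s = dt_s, time = (seq_len(n) - 0.5) * dt_s,
         stage = as.character(stage), phase = as.numeric(phase),
         sop = if (is.null(sop)) NULL else as.numeric(sop),
         counts = as.integer(counts)),
    class = "covariate_series"
  )
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("<covariate_series> %d bins of %.3g s (%.2f h), %d events%s\n",
              length(x$counts), x$dt_s,
              length(x$counts) * x$dt_s / 3600, sum(x$counts),
              if (is.null(x$sop)) ", no SOP" else ""))
  invisible(x)
}

#' Assemble aligned covariates for model fitting
#'
#' Expands the hypnogram to the model grid, interpolates SO phase and SO power
#' onto bin centers, and bins the event train. Inputs whose spans disagree by
#' at most one hypnogram epoch are truncated to the common span with a
#' warning; larger mismatches are an error.
#'
#' @param train an [event_train()].
#' @param hyp a [hypnogram()].
#' @param phase data.frame with columns `time_s`, `value` giving SO phase
#'   samples (rad), or NULL for a phase-free model.
#' @param sop data.frame with columns `time_s`, `value` giving normalized SO
#'   power samples, or NULL.
#' @param dt_s model bin width in seconds (default 0.1).
#' @return a [covariate_series()].
#' @export
assemble_covariates <- function(train, hyp, phase = NULL, sop = NULL, dt_s = 0.1) {
  stopifnot(inherits(train, "event_train"), inherits(hyp, "hypnogram"))
  spans <- c(train = train$duration_s, hypnogram = hypnogram_duration(hyp))
  if (!is.null(phase)) spans <- c(spans, phase = max(phase$time_s))
  if (!is.null(sop)) spans <- c(spans, sop = max(sop$time_s))
  if (max(spans) - min(spans) > hyp$epoch_s)
    stop_validation("input spans disagree by more than one epoch (%.1f..%.1f s)",
                    min(spans), max(spans))
  if (max(spans) - min(spans) > dt_s / 2)
    warning(sprintf("inputs truncated to common span of %.1f s", min(spans)))
  duration <- min(spans)
  n <- floor(duration / dt_s)
  t_mid <- (seq_len(n) - 0.5) * dt_s
  stage <- stage_at(hyp, t_mid)
  if (is.null(phase)) {
    ph <- rep(0, n)
  } else {
    # interpolate on the circle through (cos, sin) to avoid the +/-pi seam
    c_i <- stats::approx(phase$time_s, cos(phase$value), t_mid, rule = 2)$y
    s_i <- stats::approx(phase$time_s, sin(phase$value), t_mid, rule = 2)$y
    ph <- atan2(s_i, c_i)
    ph <- wrap_angle(ph)
  }
  sop_i <- if (is.null(sop)) NULL else
    pmin(pmax(stats::approx(sop$time_s, sop$value, t_mid, rule = 2)$y, 0), 1)
  tr <- train
  if (n * dt_s < train$duration_s) {
    keep <- tr$times < n * dt_s
    tr <- event_train(tr$times[keep], n * dt_s, tr$subject_id)
  }
  counts <- bin_events(tr, dt_s)
  length(counts) <- n
  counts[is.na(counts)] <- 0L
  cs <- covariate_series(dt_s, stage, ph, sop_i, counts)
  attr(cs, "event_times") <- tr$times
  cs
}
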