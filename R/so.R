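# Slow-oscillation phase and power from a single-channel EEG trace, plus a
# naive sigma-band demo detector. The SO band is 0.4-1.5 Hz; phase follows a
# cosine convention: phase 0 at the SO peak (cortical up-state), increasing
# through the falling edge to +/-pi at the trough.

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

so_bandpass <- function(x, fs_hz, band) {
  # FIR long enough to resolve the low band edge; zero-phase so no group delay
  ord <- min(2L * floor(1.5 * fs_hz / band[1]), floor((length(x) - 1) / 3) * 2L)
  ord <- max(ord, 10L)
  b <- signal::fir1(ord, band / (fs_hz / 2), type = "pass")
  signal::filtfilt(b, x)
}

#' Slow-oscillation phase of an EEG trace
#'
#' Band-passes the signal to the SO band with a zero-phase FIR filter and
#' takes the angle of its analytic signal. Phase 0 is aligned with SO-band
#' signal maxima (up-state peak); the range is (-pi, pi].
#'
#' @param eeg numeric vector of EEG samples (any units).
#' @param fs_hz sampling rate in Hz (>= 50).
#' @param band SO band edges in Hz (default `c(0.4, 1.5)`).
#' @return numeric vector of per-sample phase in radians.
#' @export
compute_so_phase <- function(eeg, fs_hz, band = c(0.4, 1.5)) {
  if (anyNA(eeg)) stop_validation("eeg contains NA/NaN samples")
  if (fs_hz < 50)
    stop_validation("fs_hz = %.3g too low; need >= 50 Hz to resolve the SO band", fs_hz)
  if (length(eeg) < 30 * fs_hz)
    stop_validation("signal shorter than 30 s")
  bp <- so_bandpass(eeg, fs_hz, band)
  wrap_angle(Arg(analytic_signal(bp)))
}

#' Normalized slow-oscillation power (SOP)
#'
#' Sliding-window band power in dB over the 0.3-1.5 Hz band, normalized per
#' recording to `[0, 1]` by its 5th-95th percentile range (clipped). The
#' normalization makes SOP a recording-relative continuous sleep-depth index:
#' the lightest windows map near 0, the deepest near 1.
#'
#' @param eeg numeric vector of EEG samples.
#' @param fs_hz sampling rate in Hz.
#' @param window_s sliding window length in seconds (>= 4).
#' @param step_s window step in seconds.
#' @param band band edges in Hz (default `c(0.3, 1.5)`).
#' @return data.frame with columns `time_s` (window centers), `value`
#'   (normalized SOP) and `raw_db` (band power in dB before normalization).
#' @export
compute_so_power <- function(eeg, fs_hz, window_s = 4, step_s = 2,
                             band = c(0.3, 1.5)) {
  if (anyNA(eeg)) stop_validation("eeg contains NA/NaN samples")
  if (window_s < 4)
    stop_validation("window_s = %.3g too short; need >= 4 s (about 2 SO cycles)",
                    window_s)
  nw <- round(window_s * fs_hz)
  ns <- max(1L, round(step_s * fs_hz))
  if (nw > length(eeg)) stop_validation("signal shorter than one window")
  starts <- seq(1L, length(eeg) - nw + 1L, by = ns)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  freqs <- (seq_len(nw) - 1) / nw * fs_hz
  in_band <- freqs >= band[1] & freqs <= band[2]
  pw <- vapply(starts, function(s) {
    seg <- eeg[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * taper
    mean(Mod(stats::fft(seg)[in_band])^2)
  }, numeric(1))
  raw_db <- 10 * log10(pmax(pw, .Machine$double.xmin))
  data.frame(time_s = (starts - 1 + nw / 2) / fs_hz,
             value = normalize_sop(raw_db), raw_db = raw_db)
}

#' Percentile normalization of SOP to `[0, 1]`
#'
#' @param db numeric vector of band power in dB.
#' @param probs lower/upper percentiles mapped to 0 and 1 (default 5th/95th).
#' @return values linearly rescaled and clipped to `[0, 1]`; a (near)
#'   constant input maps to 0.5.
#' @export
normalize_sop <- function(db, probs = c(0.05, 0.95)) {
  q <- stats::quantile(db, probs, names = FALSE, na.rm = TRUE)
  if (diff(q) < 1e-9) return(rep(0.5, length(db)))
  pmin(pmax((db - q[1]) / diff(q), 0), 1)
}

#' Naive sigma-band spindle detector (demo fixture only)
#'
#' Thresholds the smoothed 12-16 Hz analytic envelope and reports one event
#' per suprathreshold run (at the envelope peak). This is a plumbing fixture
#' for end-to-end demos on raw EEG; it is not a validated spindle detector
#' and carries no accuracy claims.
#'
#' @param eeg numeric vector of EEG samples.
#' @param fs_hz sampling rate in Hz.
#' @param band sigma band in Hz (default `c(12, 16)`).
#' @param threshold_quantile envelope quantile used as the detection
#'   threshold (default 0.9).
#' @param min_dur_s minimum suprathreshold duration in seconds (default 0.4).
#' @param subject_id label for the returned train.
#' @return an [event_train()] of detected peak times.
#' @export
detect_spindles_sigma <- function(eeg, fs_hz, band = c(12, 16),
                                  threshold_quantile = 0.9, min_dur_s = 0.4,
                                  subject_id = "subject") {
  if (fs_hz < 2.5 * band[2])
    stop_validation("fs_hz too low for the %g-%g Hz band", band[1], band[2])
  ord <- max(10L, 2L * floor(1.5 * fs_hz / band[1]))
  b <- signal::fir1(ord, band / (fs_hz / 2), type = "pass")
  env <- Mod(analytic_signal(signal::filtfilt(b, eeg)))
  k <- max(1L, round(0.2 * fs_hz))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  thr <- stats::quantile(env, threshold_quantile, names = FALSE)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dur_s * fs_hz
  times <- vapply(which(keep), function(i) {
    seg <- starts[i]:ends[i]
    (seg[which.max(env[seg])] - 0.5) / fs_hz
  }, numeric(1))
  event_train(sort(times), length(eeg) / fs_hz, subject_id)
}
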