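# Synthetic-night generator. Nights are produced from the same conditional
# intensity model the fitter estimates: a Markov-chain hypnogram on 30-s
# epochs, a band-limited slow-oscillation proxy providing phase and a
# normalized SO-power (SOP) series tied to stage depth, and a spindle train
# sampled bin-by-bin from log lambda = stage + phase + stage-phase +
# (optional SOP terms) + spline history, with the history evaluated causally
# from the already-generated events.

#' Ground-truth generative parameters
#'
#' @param stage_log_rates named numeric (N1, N2, N3, REM, Wake) of baseline
#'   log rates in log(events/s). `-Inf` is allowed and yields no events in
#'   that stage; finite values must satisfy `exp(rate) <= 2` events/s.
#' @param phase_beta global phase pair `(beta1, beta2)`.
#' @param stage_phase_beta named list of per-stage phase-offset pairs
#'   (reference stage N2 must be `c(0, 0)` to match the fitted
#'   parameterization).
#' @param sop_alpha `(alpha1, alpha2)` for the quadratic SOP term, or NULL.
#' @param sop_phase_beta `(gamma1, gamma2)` for the SOP-phase interaction,
#'   or NULL.
#' @param intercept baseline log rate used when the stage block is absent
#'   (SOP-based models), or NULL.
#' @param history_coeffs spline control values `h_k` (0 = no history effect).
#' @param history_knots lag knots in seconds (strictly increasing, within
#'   `[0, 90]`).
#' @param tension cardinal-spline tension.
#' @param history_mode `"last"` (modulation from the most recent event only,
#'   matching the fitted model) or `"sum"` (kernels of all past events in
#'   range add on the log scale; a robustness variant).
#' @param seed integer seed attached to these parameters.
#' @return object of class `true_parameters`.
#' @export
true_parameters <- function(stage_log_rates, phase_beta = c(0, 0),
                            stage_phase_beta = NULL, sop_alpha = NULL,
                            sop_phase_beta = NULL, intercept = NULL,
                            history_coeffs = numeric(0),
                            history_knots = KNOTS_SHORT, tension = 0.5,
                            history_mode = c("last", "sum"), seed = 1L) {
  history_mode <- match.arg(history_mode)
  if (!is.null(stage_log_rates)) {
    if (!all(STAGES %in% names(stage_log_rates)))
      stop_validation("stage_log_rates must be named with all of: %s",
                      paste(STAGES, collapse = ", "))
    fin <- stage_log_rates[is.finite(stage_log_rates)]
    if (any(exp(fin) > 2))
      stop_validation("baseline rates above 2 events/s are not plausible spindle rates")
  }
  if (length(history_coeffs)) {
    if (length(history_coeffs) != length(history_knots))
      stop_validation("history_coeffs and history_knots must have equal length")
    if (any(!is.finite(history_coeffs)))
      stop_validation("history_coeffs must be finite")
  }
  if (is.null(stage_phase_beta))
    stage_phase_beta <- stats::setNames(rep(list(c(0, 0)), 5), STAGES)
  structure(list(stage_log_rates = stage_log_rates, phase_beta = phase_beta,
                 stage_phase_beta = stage_phase_beta, sop_alpha = sop_alpha,
                 sop_phase_beta = sop_phase_beta, intercept = intercept,
                 history_coeffs = history_coeffs,
                 history_knots = as.numeric(history_knots), tension = tension,
                 history_mode = history_mode, seed = as.integer(seed)),
            class = "true_parameters")
}

#' Simulation scenario
#'
#' @param duration_s total recording length in seconds.
#' @param epoch_s hypnogram epoch length (default 30 s).
#' @param stage_transition 5 x 5 row-stochastic per-epoch transition matrix
#'   over N1, N2, N3, REM, Wake (rows must sum to 1 within 1e-12).
#' @param so_freq_hz SO oscillation frequency, in `[0.4, 1.5]` Hz.
#' @param params a [true_parameters()] object.
#' @param spec the matching [model_spec()] (which terms the generative model
#'   actually uses).
#' @param sop_profile named per-stage normalized SOP levels (deeper stage ->
#'   higher SOP), or the string `"sweep"` for a slow 0-to-1 sweep
#'   independent of stage.
#' @param sweep_period_s period of the SOP sweep (default 3600 s).
#' @param name scenario label.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(duration_s, epoch_s = 30, stage_transition,
                                so_freq_hz = 0.85, params, spec,
                                sop_profile = NULL, sweep_period_s = 3600,
                                name = "custom") {
  if (duration_s <= 0) stop_validation("duration_s must be positive")
  validate_transition(stage_transition)
  if (so_freq_hz < 0.4 || so_freq_hz > 1.5)
    stop_validation("so_freq_hz must lie in [0.4, 1.5]")
  stopifnot(inherits(params, "true_parameters"), inherits(spec, "model_spec"))
  structure(list(duration_s = duration_s, epoch_s = epoch_s,
                 stage_transition = stage_transition, so_freq_hz = so_freq_hz,
                 params = params, spec = spec, sop_profile = sop_profile,
                 sweep_period_s = sweep_period_s, name = name),
            class = "simulation_scenario")
}

validate_transition <- function(P) {
  if (!is.matrix(P) || any(dim(P) != 5))
    stop_validation("stage_transition must be a 5 x 5 matrix")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop_validation("stage_transition rows must be nonnegative and sum to 1 (within 1e-12)")
  invisible(P)
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  stats::setNames(v / sum(v), STAGES)
}

#' Simulate a hypnogram from a stage-transition Markov chain
#'
#' @param duration_s recording length (>= `epoch_s`).
#' @param epoch_s epoch length in seconds.
#' @param stage_transition row-stochastic 5 x 5 matrix over N1, N2, N3, REM,
#'   Wake.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param init_stage starting stage; NULL draws from the chain's stationary
#'   distribution.
#' @return a [hypnogram()] with `ceiling(duration_s / epoch_s)` epochs.
#' @export
simulate_hypnogram <- function(duration_s, epoch_s = 30, stage_transition,
                               seed = NULL, init_stage = NULL) {
  validate_transition(stage_transition)
  if (duration_s < epoch_s)
    stop_validation("duration_s must be at least one epoch")
  n <- ceiling(duration_s / epoch_s)
  with_seed(seed, {
    stages <- character(n)
    stages[1] <- if (is.null(init_stage))
      sample(STAGES, 1, prob = stationary_distribution(stage_transition))
    else match.arg(init_stage, STAGES)
    if (n > 1) for (i in 2:n) {
      stages[i] <- STAGES[sample.int(5, 1,
        prob = stage_transition[match(stages[i - 1], STAGES), ])]
    }
    hypnogram(stages, epoch_s)
  })
}

#' Simulate slow-oscillation phase and power covariates
#'
#' Generates a band-limited SO proxy `A(t) cos(2 pi f t)` on a regular grid.
#' The returned phase is 0 exactly at signal maxima; SOP is the amplitude
#' envelope in dB normalized to `[0, 1]` by its 5th-95th percentile range.
#'
#' @param duration_s length in seconds.
#' @param dt_s grid step (0 < dt_s <= 0.5 and fine enough to resolve the
#'   oscillation).
#' @param so_freq_hz oscillation frequency in `[0.4, 1.5]` Hz: a scalar, or
#'   a per-bin vector of instantaneous frequencies (e.g. a slow chirp).
#' @param amplitude_profile scalar, per-bin vector, or function of time
#'   giving the envelope `A(t) > 0`.
#' @param seed unused for the deterministic proxy; accepted for interface
#'   stability.
#' @return data.frame with columns `time_s`, `phase`, `sop`; attributes
#'   `raw_db` (envelope in dB) and `signal` (the SO proxy itself).
#' @export
simulate_so_covariates <- function(duration_s, dt_s, so_freq_hz,
                                   amplitude_profile = 1, seed = NULL) {
  if (dt_s <= 0 || dt_s > 0.5)
    stop_validation("dt_s must lie in (0, 0.5]")
  if (any(so_freq_hz < 0.4) || any(so_freq_hz > 1.5))
    stop_validation("so_freq_hz must lie in [0.4, 1.5]")
  if (dt_s > 1 / (4 * max(so_freq_hz)))
    stop_validation("dt_s = %.3g too coarse to resolve %.3g Hz", dt_s,
                    max(so_freq_hz))
  n <- floor(duration_s / dt_s)
  t_mid <- (seq_len(n) - 0.5) * dt_s
  f <- if (length(so_freq_hz) == 1) rep(so_freq_hz, n) else {
    if (length(so_freq_hz) != n)
      stop_validation("so_freq_hz vector must have one value per bin (%d)", n)
    so_freq_hz
  }
  # instantaneous phase = 2 pi * integral of f; for constant f this is 2 pi f t
  theta <- 2 * pi * (cumsum(f) - f / 2) * dt_s
  A <- if (is.function(amplitude_profile)) amplitude_profile(t_mid)
       else if (length(amplitude_profile) == 1) rep(amplitude_profile, n)
       else amplitude_profile
  if (length(A) != n || any(A <= 0))
    stop_validation("amplitude_profile must be positive with one value per bin")
  raw_db <- 20 * log10(A)
  out <- data.frame(time_s = t_mid, phase = wrap_angle(theta),
                    sop = normalize_sop(raw_db))
  attr(out, "raw_db") <- raw_db
  attr(out, "signal") <- A * cos(theta)
  out
}

# Per-bin covariates of a scenario evaluated analytically at times t.
scenario_covariates <- function(scenario, hyp, t) {
  stage <- stage_at(hyp, t)
  phase <- wrap_angle(2 * pi * scenario$so_freq_hz * t)
  sop <- if (identical(scenario$sop_profile, "sweep"))
    0.5 + 0.5 * sin(2 * pi * t / scenario$sweep_period_s)
  else if (is.null(scenario$sop_profile)) NULL
  else unname(unlist(scenario$sop_profile)[stage])
  list(stage = stage, phase = phase, sop = sop)
}

# Non-history log intensity per bin from the true parameters.
scenario_eta0 <- function(scenario, covs) {
  p <- scenario$params
  spec <- scenario$spec
  n <- length(covs$phase)
  eta <- if (spec$stage) {
    unname(p$stage_log_rates[covs$stage])
  } else {
    rep(p$intercept, n)
  }
  if (spec$sop)
    eta <- eta + p$sop_alpha[1] * covs$sop + p$sop_alpha[2] * covs$sop^2
  if (spec$phase) {
    b1 <- rep(p$phase_beta[1], n)
    b2 <- rep(p$phase_beta[2], n)
    if (spec$stage_phase) {
      off <- do.call(rbind, p$stage_phase_beta)[covs$stage, , drop = FALSE]
      b1 <- b1 + off[, 1]
      b2 <- b2 + off[, 2]
    }
    if (spec$sop_phase) {
      b1 <- b1 + p$sop_phase_beta[1] * covs$sop
      b2 <- b2 + p$sop_phase_beta[2] * covs$sop
    }
    eta <- eta + b1 * cos(covs$phase) + b2 * sin(covs$phase)
  }
  eta
}

#' True history modulation curve of a scenario
#'
#' @param scenario a [simulation_scenario()].
#' @param lag_grid lags in seconds.
#' @return data.frame of class `history_curve` (degenerate CI equal to the
#'   curve), for comparing fitted curves against ground truth.
#' @export
true_history_curve <- function(scenario, lag_grid = seq(0, 15, by = 0.05)) {
  p <- scenario$params
  m <- if (length(p$history_coeffs)) {
    basis <- history_basis(p$history_knots, p$tension)
    exp(eval_history_spline(basis, p$history_coeffs, lag_grid))
  } else rep(1, length(lag_grid))
  out <- data.frame(lag = lag_grid, modulation = m, ci_low = m, ci_high = m)
  class(out) <- c("history_curve", "data.frame")
  out
}

#' Simulate a history-dependent spindle train from a scenario
#'
#' Discrete-time sampling of the conditional-intensity model: in each bin an
#' event occurs with probability `1 - exp(-lambda(t | H_t) dt)`, with the
#' history term evaluated causally from the events already generated
#' (by default from the most recent event only, matching the fitted model).
#'
#' @param scenario a [simulation_scenario()].
#' @param dt_s simulation bin width (default 0.05 s, finer than the fitting
#'   grid so at most one event falls in a bin).
#' @param seed integer seed; defaults to the scenario's parameter seed. NULL
#'   uses the ambient RNG stream.
#' @param hyp optional pre-simulated [hypnogram()] (drawn from the scenario's
#'   chain when omitted).
#' @return an [event_train()] with the hypnogram attached as attribute
#'   `hypnogram`.
#' @export
simulate_event_train <- function(scenario, dt_s = 0.05,
                                 seed = scenario$params$seed, hyp = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  with_seed(seed, {
    if (is.null(hyp))
      hyp <- simulate_hypnogram(scenario$duration_s, scenario$epoch_s,
                                scenario$stage_transition)
    n <- floor(scenario$duration_s / dt_s)
    t_mid <- (seq_len(n) - 0.5) * dt_s
    covs <- scenario_covariates(scenario, hyp, t_mid)
    eta0 <- scenario_eta0(scenario, covs)
    if (any(is.nan(eta0)))
      stop("non-finite log intensity in simulation; check parameters",
           call. = FALSE)
    p <- scenario$params
    has_hist <- length(p$history_coeffs) > 0
    if (has_hist) {
      basis <- history_basis(p$history_knots, p$tension)
      k_max <- ceiling(basis$max_lag_s / dt_s)
      lm_lookup <- eval_history_spline(basis, p$history_coeffs,
                                       seq_len(k_max) * dt_s)
    } else {
      k_max <- 0L
      lm_lookup <- numeric(0)
    }
    peak <- max(eta0[is.finite(eta0)], -Inf) + max(lm_lookup, 0)
    if (is.finite(peak) && exp(peak) * dt_s >= 0.2)
      stop_validation("dt_s too coarse: max lambda * dt = %.3g >= 0.2",
                      exp(peak) * dt_s)
    u <- stats::runif(n)
    times <- if (p$history_mode == "last" || !has_hist)
      walk_last_event(u, eta0, lm_lookup, k_max, dt_s)
    else
      walk_sum_kernels(u, eta0, lm_lookup, k_max, dt_s)
    train <- event_train(t_mid[times], scenario$duration_s,
                         subject_id = scenario$name)
    attr(train, "hypnogram") <- hyp
    train
  })
}

# Renewal-style walk: modulation from the most recent event only. Each bin
# is examined exactly once against its pre-drawn uniform.
walk_last_event <- function(u, eta0, lm_lookup, k_max, dt_s) {
  n <- length(u)
  p0 <- 1 - exp(-exp(eta0) * dt_s)
  events <- integer(512)
  n_ev <- 0L
  last <- -Inf
  cur <- 1L
  chunk <- 8192L
  while (cur <= n) {
    in_hist <- k_max > 0L && (cur - last) <= k_max
    if (in_hist) {
      hi <- min(last + k_max, n)
      j <- cur:hi
      pj <- 1 - exp(-exp(eta0[j] + lm_lookup[j - last]) * dt_s)
      hit <- which(u[j] < pj)[1]
    } else {
      hi <- min(cur + chunk - 1L, n)
      j <- cur:hi
      hit <- which(u[j] < p0[j])[1]
    }
    if (!is.na(hit)) {
      b <- cur + hit - 1L
      n_ev <- n_ev + 1L
      if (n_ev > length(events)) events <- c(events, integer(length(events)))
      events[n_ev] <- b
      last <- b
      cur <- b + 1L
    } else {
      cur <- hi + 1L
    }
  }
  events[seq_len(n_ev)]
}

# Robustness variant: log-modulations of all in-range past events add.
walk_sum_kernels <- function(u, eta0, lm_lookup, k_max, dt_s) {
  n <- length(u)
  events <- integer(0)
  recent <- integer(0)
  for (i in seq_len(n)) {
    if (length(recent)) {
      recent <- recent[i - recent <= k_max]
      lm <- sum(lm_lookup[i - recent])
    } else lm <- 0
    if (u[i] < 1 - exp(-exp(eta0[i] + lm) * dt_s)) {
      events <- c(events, i)
      recent <- c(recent, i)
    }
  }
  events
}

#' Simulate a full night: hypnogram, covariates and spindle train
#'
#' Convenience wrapper producing everything the fitting pipeline needs: the
#' event train simulated at a fine grid, plus the covariate series assembled
#' on the model grid (covariates evaluated analytically at model-bin
#' centers; event times carried at simulation resolution).
#'
#' @param scenario a [simulation_scenario()].
#' @param dt_s simulation bin width (default 0.05 s).
#' @param fit_dt_s model bin width for the returned covariates (default
#'   0.1 s).
#' @param seed integer seed; defaults to the scenario's parameter seed.
#' @param subject_id label for the recording.
#' @return list of class `recording_bundle` with `train`, `hypnogram`,
#'   `cov` (a [covariate_series()]), `scenario`.
#' @export
simulate_night <- function(scenario, dt_s = 0.05, fit_dt_s = 0.1,
                           seed = scenario$params$seed,
                           subject_id = scenario$name) {
  train <- simulate_event_train(scenario, dt_s, seed = seed)
  hyp <- attr(train, "hypnogram")
  n <- floor(scenario$duration_s / fit_dt_s)
  t_mid <- (seq_len(n) - 0.5) * fit_dt_s
  covs <- scenario_covariates(scenario, hyp, t_mid)
  counts <- bin_events(train, fit_dt_s)
  length(counts) <- n
  counts[is.na(counts)] <- 0L
  cov <- covariate_series(fit_dt_s, covs$stage, covs$phase, covs$sop, counts)
  attr(cov, "event_times") <- train$times
  train$subject_id <- subject_id
  structure(list(train = train, hypnogram = hyp, cov = cov,
                 scenario = scenario),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> '%s': %d events over %.1f h\n",
              x$train$subject_id, length(x$train$times),
              x$train$duration_s / 3600))
  invisible(x)
}

#' Registered paper-like simulation scenarios
#'
#' Scenarios are stored in a JSON registry shipped with the package
#' (`system.file("extdata", "scenarios.json", package = "spindlepp")`).
#' `"paper_default"` is an 8-h night whose realized N2 spindle density is
#' about 11 events/min with a refractory period near 1.8 s and a history
#' peak near 1.9 at 3.5 s; `"null_history"` removes the history term;
#' `"phase_shift"` is a history-free variant with stage-dependent preferred
#' phase (N2 at 0, N3 at -pi/8); `"history_only"` has equal stage rates and
#' no phase coupling; `"phase_depth"` sweeps SOP over the night with the
#' preferred phase drifting from 0 (SOP 0) to -pi/8 (SOP 1).
#'
#' @param name registered scenario name.
#' @param duration_s override the registered duration (seconds).
#' @param seed override the registered seed.
#' @return a [simulation_scenario()].
#' @export
paper_like_scenario <- function(name = "paper_default", duration_s = NULL,
                                seed = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop_validation("unknown scenario '%s'; registered: %s", name,
                    paste(names(reg), collapse = ", "))
  r <- reg[[name]]
  params <- true_parameters(
    stage_log_rates = if (is.null(r$stage_log_rates)) NULL
                      else unlist(r$stage_log_rates)[STAGES],
    phase_beta = unlist(r$phase_beta),
    stage_phase_beta = lapply(r$stage_phase_beta, unlist),
    sop_alpha = if (is.null(r$sop_alpha)) NULL else unlist(r$sop_alpha),
    sop_phase_beta = if (is.null(r$sop_phase_beta)) NULL
                     else unlist(r$sop_phase_beta),
    intercept = r$intercept,
    history_coeffs = if (is.null(r$history_coeffs)) numeric(0)
                     else unlist(r$history_coeffs),
    history_knots = if (is.null(r$history_knots)) KNOTS_SHORT
                    else unlist(r$history_knots),
    history_mode = if (is.null(r$history_mode)) "last" else r$history_mode,
    seed = if (is.null(seed)) r$seed else seed)
  pi_s <- unlist(r$stationary)[STAGES]
  P <- r$dwell * diag(5) + (1 - r$dwell) * matrix(pi_s, 5, 5, byrow = TRUE)
  dimnames(P) <- list(STAGES, STAGES)
  simulation_scenario(
    duration_s = if (is.null(duration_s)) r$duration_s else duration_s,
    epoch_s = r$epoch_s, stage_transition = P, so_freq_hz = r$so_freq_hz,
    params = params, spec = parse_spec_token(r$spec),
    sop_profile = r$sop_profile, name = name)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used to generate preferred-phase
#' populations for circular-statistics calibration studies.
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop_validation("kappa must be nonnegative")
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  wrap_angle(out + mu)
}

#' True coefficient vector of a scenario in fitted-model naming
#'
#' Arranges the generative parameters in the same named layout as the
#' coefficients of a model fitted with the scenario's own spec, for
#' parameter-recovery and CI-coverage checks.
#'
#' @param scenario a [simulation_scenario()].
#' @return named numeric vector.
#' @export
true_coefficient_vector <- function(scenario) {
  p <- scenario$params
  spec <- scenario$spec
  out <- numeric(0)
  if (spec$stage)
    out <- c(out, stats::setNames(unname(p$stage_log_rates[STAGES]),
                                  paste0("stage_", STAGES)))
  else out <- c(out, "(Intercept)" = p$intercept)
  if (spec$phase)
    out <- c(out, phase_cos = p$phase_beta[1], phase_sin = p$phase_beta[2])
  if (spec$stage_phase)
    for (s in STAGES)
      out <- c(out, stats::setNames(p$stage_phase_beta[[s]],
                                    paste0("stagephase_", s, c("_cos", "_sin"))))
  if (spec$sop)
    out <- c(out, sop = p$sop_alpha[1], sop_sq = p$sop_alpha[2])
  if (spec$sop_phase)
    out <- c(out, sopphase_cos = p$sop_phase_beta[1],
             sopphase_sin = p$sop_phase_beta[2])
  if (spec$history != "none")
    out <- c(out, stats::setNames(p$history_coeffs,
                                  sprintf("hist_%02d", seq_along(p$history_coeffs))))
  out
}

scenario_registry <- function() {
  path <- system.file("extdata", "scenarios.json", package = "spindlepp")
  if (path == "") path <- file.path("inst", "extdata", "scenarios.json")
  jsonlite::read_json(path)
}
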