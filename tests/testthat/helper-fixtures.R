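# Shared fixtures built in code: small scenarios and hand-made designs.

stage_names <- c("N1", "N2", "N3", "REM", "Wake")

uniform_transition <- function() {
  P <- matrix(0.2, 5, 5, dimnames = list(stage_names, stage_names))
  P
}

# Homogeneous-rate scenario: same baseline in every stage, no phase or
# history terms unless supplied.
const_rate_scenario <- function(rate_per_min, duration_s = 900, seed = 1,
                                history_coeffs = numeric(0),
                                history_knots = c(0, 0.5, 1, 1.5, 2, 2.5, 3,
                                                  3.5, 4, 5, 6.5, 8, 10,
                                                  12.5, 15),
                                phase_beta = c(0, 0)) {
  has_hist <- length(history_coeffs) > 0
  simulation_scenario(
    duration_s, 30, uniform_transition(), 0.85,
    true_parameters(
      stats::setNames(rep(log(rate_per_min / 60), 5), stage_names),
      phase_beta = phase_beta,
      history_coeffs = history_coeffs, history_knots = history_knots,
      seed = seed),
    model_spec(stage = TRUE, phase = any(phase_beta != 0),
               history = if (has_hist) "short" else "none"))
}

# Covariate series for a constant-stage recording with cosine SO phase.
simple_cov <- function(n_bins, dt_s = 0.1, stage = "N2", counts = NULL,
                       so_freq = 0.85) {
  t_mid <- (seq_len(n_bins) - 0.5) * dt_s
  if (is.null(counts)) counts <- integer(n_bins)
  covariate_series(dt_s, rep(stage, n_bins),
                   spindlepp::wrap_angle(2 * pi * so_freq * t_mid),
                   NULL, counts)
}

# Hand-made two-block design used for exact-additivity synergy constructions.
manual_design <- function(X, y, dt_s = 0.1, groups = NULL) {
  structure(list(X = X, y = y, exposure = dt_s,
                 term_groups = groups %||% list(intercept = colnames(X)),
                 spec = model_spec(stage = FALSE, dt_s = dt_s), basis = NULL),
            class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_wrapped_equal <- function(a, b, tol = 1e-8) {
  d <- spindlepp::wrap_angle(a - b)
  expect_lt(max(abs(d)), tol)
}
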