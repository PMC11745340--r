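# A fitted-model stub with a chosen history coefficient vector and
# covariance, for exercising curve/CI machinery without a fit.
stub_history_model <- function(h, V = diag(length(h)) * 0, basis = history_basis()) {
  cols <- sprintf("hist_%02d", seq_along(h))
  dimnames(V) <- list(cols, cols)
  structure(list(coefficients = stats::setNames(h, cols), estimated = cols,
                 dropped = character(0), vcov = V, term_groups = list(history = cols),
                 spec = model_spec(stage = TRUE, history = "short"),
                 basis = basis, dt_s = 0.1),
            class = "spindle_ppglm")
}

test_that("null history coefficients give a flat curve at 1", {
  m <- stub_history_model(rep(0, 15), diag(15) * 0.01)
  cur <- history_modulation_curve(m, seq(0, 15, by = 0.1))
  expect_equal(cur$modulation, rep(1, nrow(cur)), tolerance = 1e-12)
  expect_true(all(cur$ci_low <= 1 & cur$ci_high >= 1))
})

test_that("modulation is exactly 1 beyond the last knot of a long basis", {
  b <- history_basis(c(0, 1, 2, 4, 8, 20, 50), tension = 0.5)
  m <- stub_history_model(c(-2, -1, 0.5, 0.3, 0.1, 0.05, 0), basis = b)
  m$spec <- model_spec(stage = TRUE, history = "long")
  cur <- history_modulation_curve(m, c(50.0001, 60, 89.9))
  expect_equal(cur$modulation, rep(1, 3))
  expect_error(history_modulation_curve(m, c(0, 91)), "lag_grid")
})

test_that("feature extraction reproduces analytically placed CI crossings", {
  lag <- seq(0, 15, by = 0.05)
  pw <- function(xs, ys) stats::approx(xs, ys, lag, rule = 2)$y
  mod <- pw(c(0, 1.9, 3.5, 6, 15), c(0.05, 1.0, 1.9, 1.0, 1.0))
  hi <- pw(c(0, 1.8, 3.5, 15), c(0.2, 1.0, 2.2, 1.3))
  lo <- pw(c(0, 2.0, 3.45, 4.9, 15), c(0.02, 1.0, 1.5, 1.0, 0.9))
  f <- extract_history_features(
    data.frame(lag = lag, modulation = mod, ci_low = lo, ci_high = hi))
  expect_equal(f$refractory_s, 1.8, tolerance = 1e-9)
  expect_equal(f$excitatory_s, 2.9, tolerance = 1e-9)
  expect_equal(f$peak_time_s, 3.5, tolerance = 1e-9)
  expect_equal(f$peak_height, 1.9, tolerance = 1e-9)
})

test_that("a flat nonsignificant curve has empty windows and NaN peak", {
  lag <- seq(0, 15, by = 0.1)
  f <- extract_history_features(
    data.frame(lag = lag, modulation = rep(1, length(lag)),
               ci_low = rep(0.9, length(lag)), ci_high = rep(1.1, length(lag))))
  expect_equal(f$refractory_s, 0)
  expect_equal(f$excitatory_s, 0)
  expect_true(is.nan(f$peak_time_s))
  expect_true(is.nan(f$peak_height))
})

test_that("the longest of several excitatory runs wins and hosts the peak", {
  lag <- seq(0, 15, by = 0.01)
  lo <- rep(0.95, length(lag))
  lo[lag >= 2 & lag <= 3] <- 1.2        # 1-s run, taller modulation
  lo[lag >= 6 & lag <= 9] <- 1.1        # 3-s run
  mod <- lo + 0.3
  f <- extract_history_features(
    data.frame(lag = lag, modulation = mod, ci_low = lo, ci_high = mod + 0.5))
  expect_equal(f$excitatory_s, 3, tolerance = 0.02)
  expect_true(f$peak_time_s >= 6 && f$peak_time_s <= 9)
})

test_that("scale consistency: zero history gives features (0, 0, NaN, NaN, 1)", {
  long_knots <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6.5, 8, 10, 12.5, 15,
                  20, 30, 40, 50, 60, 75, 90)
  m <- stub_history_model(rep(0, 22), diag(22) * 1e-4,
                          basis = history_basis(long_knots))
  cur <- history_modulation_curve(m, seq(0, 90, by = 0.25))
  f <- extract_history_features(cur)
  expect_equal(f$refractory_s, 0)
  expect_equal(f$excitatory_s, 0)
  expect_true(is.nan(f$peak_height))
  expect_equal(f$infraslow_multiplier, 1, tolerance = 1e-9)
})

test_that("infraslow multiplier integrates the 40-70 s window by trapezoid", {
  lag <- seq(0, 90, by = 0.5)
  flat <- data.frame(lag = lag, modulation = rep(1, length(lag)),
                     ci_low = 1, ci_high = 1)
  expect_equal(infraslow_multiplier(flat), 1)
  two <- flat; two$modulation <- ifelse(lag >= 40 & lag <= 70, 2, 1)
  expect_equal(infraslow_multiplier(two), 2)
  ramp <- flat; ramp$modulation <- 1 + pmin(pmax((lag - 40) / 30, 0), 1)
  expect_equal(infraslow_multiplier(ramp), 1.5, tolerance = 1e-12)
  short <- flat[flat$lag <= 60, ]
  expect_error(infraslow_multiplier(short), "span")
})

test_that("phase tuning arithmetic matches atan2/Pythagoras", {
  stub_phase <- function(b1, b2) {
    cols <- c("phase_cos", "phase_sin")
    V <- diag(2) * 1e-4; dimnames(V) <- list(cols, cols)
    structure(list(coefficients = stats::setNames(c(b1, b2), cols),
                   estimated = cols, dropped = character(0), vcov = V,
                   term_groups = list(phase = cols),
                   spec = model_spec(stage = FALSE, phase = TRUE)),
              class = "spindle_ppglm")
  }
  pt <- phase_tuning(stub_phase(1, 0))
  expect_equal(pt$magnitude, 1)
  expect_equal(pt$phi_pref, 0)
  expect_equal(phase_tuning(stub_phase(0, 1))$phi_pref, pi / 2)
  pt2 <- phase_tuning(stub_phase(-0.3, 0.4))
  expect_equal(pt2$magnitude, 0.5, tolerance = 1e-12)
  expect_equal(pt2$phi_pref, atan2(0.4, -0.3), tolerance = 1e-12)
  expect_equal(pt2$phi_pref, 2.2143, tolerance = 1e-4)
  # phi_pref invariant under positive rescaling of the pair
  pt3 <- phase_tuning(stub_phase(-0.3 * 7, 0.4 * 7))
  expect_equal(pt3$phi_pref, pt2$phi_pref, tolerance = 1e-12)
})

test_that("the fitted phase term equals M cos(phi - phi_pref) identically", {
  nt <- simulate_night(const_rate_scenario(10, duration_s = 1800,
                                           phase_beta = c(0.25, -0.15)),
                       seed = 21)
  fit <- suppressWarnings(fit_point_process_glm(
    build_design_matrix(nt$cov, parse_spec_token("stage+phase"))))
  b <- coef(fit)[c("phase_cos", "phase_sin")]
  pt <- phase_tuning(fit)
  phi <- seq(-pi, pi, length.out = 10001)
  expect_equal(b[[1]] * cos(phi) + b[[2]] * sin(phi),
               pt$magnitude * cos(phi - pt$phi_pref), tolerance = 1e-12)
})

test_that("huge angular uncertainty is flagged as no preferred phase", {
  cols <- c("phase_cos", "phase_sin")
  V <- diag(2) * 100; dimnames(V) <- list(cols, cols)
  m <- structure(list(coefficients = stats::setNames(c(0.01, 0), cols),
                      estimated = cols, dropped = character(0), vcov = V,
                      term_groups = list(phase = cols),
                      spec = model_spec(stage = FALSE, phase = TRUE)),
                 class = "spindle_ppglm")
  expect_false(phase_tuning(m)$has_preferred_phase)
})

test_that("preferred phase vs depth is flat without interactions and drifts with them", {
  mk <- function(gamma) {
    cols <- c("(Intercept)", "phase_cos", "phase_sin", "sop", "sop_sq",
              "sopphase_cos", "sopphase_sin")
    co <- stats::setNames(c(-2, 0.22, 0, 0.5, -0.2, gamma), cols)
    V <- diag(7) * 1e-6; dimnames(V) <- list(cols, cols)
    structure(list(coefficients = co, estimated = cols, dropped = character(0),
                   vcov = V,
                   term_groups = list(intercept = cols[1], phase = cols[2:3],
                                      sop = cols[4:5], sop_phase = cols[6:7]),
                   spec = model_spec(stage = FALSE, sop = TRUE, phase = TRUE,
                                     sop_phase = TRUE)),
              class = "spindle_ppglm")
  }
  flat <- preferred_phase_vs_depth(mk(c(0, 0)))
  expect_equal(flat$phi_pref, rep(0, nrow(flat)), tolerance = 1e-12)
  drift <- preferred_phase_vs_depth(mk(0.22 * c(cos(-pi / 8) - 1, sin(-pi / 8))),
                                    sop_grid = c(0, 0.5, 1))
  expect_equal(drift$phi_pref[1], 0, tolerance = 1e-12)
  expect_equal(drift$phi_pref[3], -pi / 8, tolerance = 1e-12)
  expect_error(preferred_phase_vs_depth(mk(c(0, 0)), sop_grid = c(-0.1, 0.5)),
               "0, 1")
})
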