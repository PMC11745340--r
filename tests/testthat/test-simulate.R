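test_that("hypnogram simulation: absorbing chain, epoch count, validation", {
  I5 <- diag(5); dimnames(I5) <- list(stage_names, stage_names)
  hyp <- simulate_hypnogram(300, 30, I5, seed = 1, init_stage = "N2")
  expect_equal(hyp$stages, rep("N2", 10))
  expect_length(simulate_hypnogram(300, 30, uniform_transition(), seed = 1)$stages,
                10)
  bad <- uniform_transition(); bad[1, 1] <- 0.5
  expect_error(simulate_hypnogram(300, 30, bad), "sum to 1")
  expect_error(simulate_hypnogram(10, 30, uniform_transition()), "epoch")
})

test_that("uniform-chain occupancy matches the stationary distribution", {
  hyp <- simulate_hypnogram(10000 * 30, 30, uniform_transition(), seed = 2)
  occ <- table(factor(hyp$stages, levels = stage_names)) / 10000
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(occ - 0.2) < 3 * se))
})

test_that("hypnogram draws are reproducible under a seed", {
  h1 <- simulate_hypnogram(3600, 30, uniform_transition(), seed = 33)
  h2 <- simulate_hypnogram(3600, 30, uniform_transition(), seed = 33)
  expect_identical(h1$stages, h2$stages)
})

test_that("simulated SO covariates follow the cosine phase convention", {
  so <- simulate_so_covariates(600, 0.1, 0.8)
  sig <- attr(so, "signal")
  # phase at signal maxima is 0 within one bin of phase advance
  peaks <- which(diff(sign(diff(sig))) == -2) + 1
  expect_lt(max(abs(so$phase[peaks])), 2 * pi * 0.8 * 0.1)
  expect_true(all(so$phase > -pi & so$phase <= pi))
})

test_that("doubling the SO amplitude adds 6.02 dB of raw power", {
  s1 <- simulate_so_covariates(300, 0.1, 0.8, amplitude_profile = 1)
  s2 <- simulate_so_covariates(300, 0.1, 0.8, amplitude_profile = 2)
  expect_equal(attr(s2, "raw_db") - attr(s1, "raw_db"),
               rep(20 * log10(2), 3000), tolerance = 1e-12)
})

test_that("chirp covariate phase matches the quadrature oracle", {
  dur <- 400; dt <- 0.1
  n <- dur / dt
  f <- seq(0.5, 1.2, length.out = n)
  so <- simulate_so_covariates(dur, dt, f)
  theta_oracle <- 2 * pi * (cumsum(f) - f / 2) * dt
  inner <- so$time_s > 5 & so$time_s < dur - 5
  expect_wrapped_equal(so$phase[inner], theta_oracle[inner], tol = 0.05)
  expect_error(simulate_so_covariates(300, 0.45, 1.5), "coarse")
})

test_that("a modulation-free constant-rate train has Poisson event counts", {
  sc <- const_rate_scenario(10, duration_s = 3600)
  tr <- simulate_event_train(sc, seed = 41)
  expect_true(all(diff(tr$times) > 0))
  # 600 expected events, 3-sigma band
  expect_lt(abs(length(tr$times) - 600), 3 * sqrt(600))
})

test_that("a hard refractory construction produces no short intervals", {
  h <- c(-50, -50, -50, -50, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  # knots 0..1.5 at -50: modulation ~0 out to 2 s by spline continuity
  sc <- const_rate_scenario(3, duration_s = 3600, seed = 5,
                            history_coeffs = h)
  tr <- simulate_event_train(sc, seed = 42)
  expect_gt(length(tr$times), 60)
  expect_gt(min(diff(tr$times)), 1.5)
})

test_that("zero baseline rate yields an empty train", {
  sc <- const_rate_scenario(1, duration_s = 600)
  sc$params$stage_log_rates[] <- -Inf
  tr <- simulate_event_train(sc, seed = 43)
  expect_length(tr$times, 0)
})

test_that("event trains are bit-identical under the same seed", {
  sc <- paper_like_scenario("paper_default", duration_s = 3600)
  t1 <- simulate_event_train(sc, seed = 44)
  t2 <- simulate_event_train(sc, seed = 44)
  expect_identical(t1$times, t2$times)
  expect_identical(attr(t1, "hypnogram")$stages, attr(t2, "hypnogram")$stages)
})

test_that("per-stage rates of a no-history no-phase night match truth", {
  P <- 0.85 * diag(5) + 0.15 * matrix(0.2, 5, 5)
  dimnames(P) <- list(stage_names, stage_names)
  rates <- c(N1 = 2, N2 = 11, N3 = 5, REM = 1, Wake = 0.5) / 60
  sc <- simulation_scenario(6 * 3600, 30, P, 0.85,
                            true_parameters(log(rates)[stage_names], seed = 1),
                            model_spec(stage = TRUE))
  tr <- simulate_event_train(sc, seed = 45)
  hyp <- attr(tr, "hypnogram")
  st_ev <- table(factor(stage_at(hyp, tr$times), levels = stage_names))
  occ_s <- table(factor(hyp$stages, levels = stage_names)) * 30
  for (s in c("N2", "N3")) {
    expected <- rates[[s]] * occ_s[[s]]
    expect_lt(abs(st_ev[[s]] - expected), 3 * sqrt(expected))
  }
})

test_that("time-rescaling under the true intensity is well calibrated", {
  # simulated trains rescaled by their own generative rate pass KS ~95%
  sc <- const_rate_scenario(12, duration_s = 900)
  pass <- vapply(1:60, function(r) {
    tr <- simulate_event_train(sc, seed = 600 + r)
    cov <- simple_cov(9000)
    cov$counts <- { cnt <- bin_events(tr, 0.1); length(cnt) <- 9000
                    cnt[is.na(cnt)] <- 0L; as.integer(cnt) }
    time_rescaling_ks(rep(12 / 60, 9000), tr, cov)$pass_05
  }, logical(1))
  expect_gt(mean(pass), 0.85)
})

test_that("the scenario registry resolves names and rejects unknowns", {
  expect_error(paper_like_scenario("nope"), "paper_default")
  sc <- paper_like_scenario("null_history")
  expect_true(all(sc$params$history_coeffs == 0))
  ps <- paper_like_scenario("phase_shift")
  n2 <- atan2(ps$params$phase_beta[2], ps$params$phase_beta[1])
  eff3 <- ps$params$phase_beta + ps$params$stage_phase_beta$N3
  expect_equal(n2, 0)
  expect_equal(atan2(eff3[2], eff3[1]), -pi / 8, tolerance = 1e-4)
})

test_that("paper-like defaults land at the registered N2 density", {
  sc <- paper_like_scenario("paper_default")
  nt <- simulate_night(sc, seed = 46)
  n2_ev <- sum(stage_at(nt$hypnogram, nt$train$times) == "N2")
  n2_min <- sum(nt$hypnogram$stages == "N2") * 0.5
  expect_equal(60 * n2_ev / (n2_min * 60), 11, tolerance = 0.12)
})

test_that("summed-kernel history mode runs and respects refractoriness", {
  sc <- const_rate_scenario(3, duration_s = 1200, seed = 6,
                            history_coeffs = c(-50, -50, -50, -50, 0.3, 0.4,
                                               0.4, 0.3, 0.2, 0.1, 0, 0, 0, 0, 0))
  sc$params$history_mode <- "sum"
  tr <- simulate_event_train(sc, seed = 47)
  expect_gt(length(tr$times), 10)
  expect_gt(min(diff(tr$times)), 1.5)
})

test_that("the von Mises sampler hits its mean direction and concentration", {
  set.seed(48)
  x <- rvonmises(4000, 0.7, 4)
  C <- mean(cos(x)); S <- mean(sin(x))
  expect_equal(atan2(S, C), 0.7, tolerance = 0.05)
  # E[cos(theta - mu)] = I1(k)/I0(k)
  expect_equal(sqrt(C^2 + S^2), besselI(4, 1) / besselI(4, 0), tolerance = 0.02)
})
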