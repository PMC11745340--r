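test_that("intercept-only fit is the closed-form Poisson mean rate", {
  set.seed(1)
  n <- 36000            # 3600 s at dt 0.1
  cnt <- integer(n)
  cnt[sample.int(n, 600)] <- 1L
  cov <- simple_cov(n, counts = cnt)
  d <- build_design_matrix(cov, model_spec(stage = FALSE))
  fit <- fit_point_process_glm(d)
  expect_equal(exp(unname(coef(fit))), 600 / 3600, tolerance = 1e-8)
})

test_that("stage-only fit reproduces per-stage empirical mean rates", {
  set.seed(2)
  hyp <- hypnogram(rep(c("N2", "N3", "REM"), each = 20), 30)  # 30 min
  times <- sort(runif(260, 0, 1790))
  times <- times[c(TRUE, diff(times) > 0.15)]
  tr <- event_train(times, 1800)
  cov <- assemble_covariates(tr, hyp, dt_s = 0.1)
  fit <- suppressWarnings(
    fit_point_process_glm(build_design_matrix(cov, model_spec(stage = TRUE))))
  for (s in c("N2", "N3", "REM")) {
    in_s <- cov$stage == s
    emp <- sum(cov$counts[in_s]) / (sum(in_s) * 0.1)
    expect_equal(exp(unname(coef(fit)[paste0("stage_", s)])), emp,
                 tolerance = 1e-7)
  }
})

test_that("toy-design coefficients match a brute-force likelihood oracle", {
  set.seed(3)
  n <- 2000
  X <- cbind(intercept = 1, x = rnorm(n))
  eta <- -2 + 0.4 * X[, 2]
  y <- as.integer(runif(n) < 1 - exp(-exp(eta) * 0.1))
  d <- manual_design(X, y)
  fit <- fit_point_process_glm(d)

  negll <- function(b) {
    mu <- exp(drop(X %*% b) + log(0.1))
    -sum(stats::dpois(y, mu, log = TRUE))
  }
  oracle <- stats::optim(c(0, 0), negll, method = "BFGS",
                         control = list(reltol = 1e-14))$par
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-6)

  # and against the standard IRLS implementation
  g <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                       offset = rep(log(0.1), n)))
  expect_equal(unname(coef(fit)), unname(g$coefficients), tolerance = 1e-8)
  expect_equal(fit$deviance, g$deviance, tolerance = 1e-8)
})

test_that("covariance equals the inverse Fisher information at the optimum", {
  set.seed(4)
  n <- 5000
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- as.integer(runif(n) < 0.05)
  fit <- fit_point_process_glm(manual_design(X, y))
  mu <- exp(drop(X %*% coef(fit)) + log(0.1))
  expect_equal(fit$vcov, solve(crossprod(X, X * mu)),
               tolerance = 1e-6, ignore_attr = TRUE)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("zero-occupancy stages are dropped with a warning", {
  cnt <- integer(600); cnt[c(100, 300, 500)] <- 1L
  cov <- simple_cov(600, counts = cnt)  # all N2
  expect_warning(
    fit <- fit_point_process_glm(build_design_matrix(cov, model_spec(stage = TRUE))),
    "zero occupancy")
  expect_true("stage_N1" %in% fit$dropped)
  expect_equal(coef(fit)[["stage_N1"]], 0)
})

test_that("log-likelihood never decreases as nested terms are added", {
  nt <- simulate_night(const_rate_scenario(10, duration_s = 1200,
                                           phase_beta = c(0.3, 0)), seed = 9)
  lls <- vapply(c("null", "stage", "stage+phase"), function(tok)
    suppressWarnings(fit_point_process_glm(
      build_design_matrix(nt$cov, parse_spec_token(tok))))$log_likelihood,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("likelihood-ratio test contracts hold", {
  nt <- simulate_night(const_rate_scenario(10, duration_s = 1200), seed = 10)
  f_null <- fit_point_process_glm(build_design_matrix(nt$cov, parse_spec_token("null")))
  f_stage <- suppressWarnings(
    fit_point_process_glm(build_design_matrix(nt$cov, parse_spec_token("stage"))))
  f_phase <- suppressWarnings(
    fit_point_process_glm(build_design_matrix(nt$cov, parse_spec_token("stage+phase"))))

  same <- likelihood_ratio_test(f_stage, f_stage)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  lrt <- likelihood_ratio_test(f_phase, f_stage)
  expect_equal(lrt$df, 2)  # the two added phase columns
  expect_gte(lrt$statistic, 0)

  expect_error(likelihood_ratio_test(f_stage, f_phase),
               "not nested|more parameters")
})

test_that("deviance fractions telescope to exactly 100", {
  nt <- simulate_night(paper_like_scenario("history_only",
                                           duration_s = 7200), seed = 11)
  toks <- c(null = "null", stage = "stage", phase = "stage+phase",
            history = "stage+phase+history15")
  fits <- lapply(toks, function(tok) suppressWarnings(
    fit_point_process_glm(build_design_matrix(nt$cov, parse_spec_token(tok)))))
  dec <- deviance_fractions(fits)
  expect_equal(sum(dec$fraction_pct, na.rm = TRUE), 100, tolerance = 1e-9)
  # one-step chain: that step explains everything
  dec1 <- deviance_fractions(fits[c(1, 4)])
  expect_equal(dec1$fraction_pct[2], 100, tolerance = 1e-12)
})

test_that("synergy index is exactly zero under constructed additivity", {
  # two disjoint bin sets with their own baselines; covariate A lives only
  # on set 1, covariate B only on set 2, so likelihoods factorize and
  # information gains add exactly
  set.seed(12)
  n <- 4000
  half <- rep(c(1, 0), each = n / 2)
  a_cov <- half * sin(seq_len(n) / 50)
  b_cov <- (1 - half) * cos(seq_len(n) / 80)
  eta <- log(0.5) + 0.8 * a_cov - 0.9 * b_cov
  y <- as.integer(runif(n) < 1 - exp(-exp(eta) * 0.1))
  base <- cbind(set1 = half, set2 = 1 - half)
  fit0 <- fit_point_process_glm(manual_design(base, y))
  fitA <- fit_point_process_glm(manual_design(cbind(base, a = a_cov), y))
  fitB <- fit_point_process_glm(manual_design(cbind(base, b = b_cov), y))
  fitAB <- fit_point_process_glm(manual_design(cbind(base, a = a_cov, b = b_cov), y))
  s <- synergy_index(fit0, fitA, fitB, fitAB)
  expect_equal(s$index, 0, tolerance = 1e-7)
  expect_equal(s$gains[["AB"]], s$gains[["A"]] + s$gains[["B"]],
               tolerance = 1e-9)
})

test_that("duplicated covariates give a negative (redundant) synergy index", {
  set.seed(13)
  n <- 4000
  x <- sin(seq_len(n) / 40)
  eta <- log(0.5) + 0.7 * x
  y <- as.integer(runif(n) < 1 - exp(-exp(eta) * 0.1))
  base <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  fit0 <- fit_point_process_glm(manual_design(base, y))
  fitA <- fit_point_process_glm(manual_design(cbind(base, a = x), y))
  fitB <- fit_point_process_glm(manual_design(cbind(base, b = x), y))
  fitAB <- suppressWarnings(
    fit_point_process_glm(manual_design(cbind(base, a = x, b = x), y)))
  s <- synergy_index(fit0, fitA, fitB, fitAB)
  expect_lt(s$index, 0)
  # pure redundancy: I_AB = I_A = I_B, so index = -I_A / I_AB = -1
  expect_equal(s$index, -1, tolerance = 1e-6)
})

test_that("KS statistic of mid-quantile uniforms is 1/(2n)", {
  for (n in c(20, 101, 500)) {
    z <- (seq_len(n) - 0.5) / n
    expect_equal(ks_uniform(sample(z))$ks_statistic, 1 / (2 * n),
                 tolerance = 1e-12)
  }
})

test_that("time rescaling needs enough events and respects the pass rule", {
  cov <- simple_cov(1000)
  tr <- event_train(seq(5, 95, by = 10)[1:5], 100)
  expect_error(time_rescaling_ks(rep(0.1, 1000), tr, cov), "at least 10")
  g <- ks_uniform((seq_len(100) - 0.5) / 100)
  expect_true(g$pass_05)
  expect_identical(g$pass_05, g$ks_statistic < 1.36 / sqrt(g$n))
})
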