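mk_curve <- function(mod, lag = NULL) {
  if (is.null(lag)) lag <- seq(0, 15, length.out = length(mod))
  out <- data.frame(lag = lag, modulation = mod, ci_low = mod, ci_high = mod)
  class(out) <- c("history_curve", "data.frame")
  out
}

test_that("curve correlation: identity, reflection and a formula oracle", {
  set.seed(31)
  a <- mk_curve(1 + 0.5 * sin(seq(0, 6, length.out = 300)))
  expect_equal(curve_correlation(a, a), 1)
  refl <- mk_curve(2 * mean(a$modulation) - a$modulation)
  expect_equal(curve_correlation(a, refl), -1)

  x <- rnorm(300); y <- rnorm(300)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(curve_correlation(x, y), oracle, tolerance = 1e-12)

  expect_error(curve_correlation(a, mk_curve(a$modulation, lag = a$lag + 1)),
               "identical lag grid")
  expect_error(curve_correlation(rep(1, 50), rnorm(50)), "zero-variance")
})

test_that("intra/inter correlation pools split by subject and night", {
  set.seed(32)
  base <- 1 + 0.5 * sin(seq(0, 6, length.out = 100))
  curves <- rbind(base + rnorm(100, sd = 0.01),   # subj 1 night 1
                  base + rnorm(100, sd = 0.01),   # subj 1 night 2
                  rev(base) + rnorm(100, sd = 0.01),  # subj 2 night 1
                  rev(base) + rnorm(100, sd = 0.01))  # subj 2 night 2
  pools <- correlation_pools(curves, c("a", "a", "b", "b"), c(1, 2, 1, 2))
  expect_length(pools$intra, 2)
  expect_length(pools$inter, 1)
  expect_true(all(pools$intra > 0.9))
  expect_lt(pools$inter, 0)
})

test_that("Watson-Williams: identical groups give F = 0, p = 1", {
  ang <- c(0.1, 0.2, -0.1, 0.05, 0.15, -0.2)
  ww <- watson_williams_test(list(ang, ang))
  expect_equal(ww$statistic, 0)
  expect_equal(ww$p_value, 1)
})

test_that("Watson-Williams separates concentrated groups and matches the formula", {
  set.seed(33)
  g1 <- rvonmises(20, 0, 8)
  g2 <- rvonmises(20, pi / 2, 8)
  ww <- watson_williams_test(list(g1, g2))
  expect_lt(ww$p_value, 0.001)

  # from-formula oracle computed independently
  R_of <- function(a) sqrt(sum(cos(a))^2 + sum(sin(a))^2)
  N <- 40; Rs <- R_of(g1) + R_of(g2); R <- R_of(c(g1, g2))
  rbar <- Rs / N
  kap <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6 else
         if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar) else
         1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  Fo <- (1 + 3 / (8 * kap)) * ((N - 2) * (Rs - R)) / ((2 - 1) * (N - Rs))
  expect_equal(ww$statistic, Fo, tolerance = 1e-12)
})

test_that("Watson-Williams is invariant to common rotation", {
  set.seed(34)
  g1 <- rvonmises(15, 0.3, 5)
  g2 <- rvonmises(15, 0.8, 5)
  w0 <- watson_williams_test(list(g1, g2))
  w1 <- watson_williams_test(list(wrap_angle(g1 + 1.1), wrap_angle(g2 + 1.1)))
  expect_equal(w1$statistic, w0$statistic, tolerance = 1e-9)
  expect_error(watson_williams_test(list(g1, numeric(0))), "at least 5|non-empty")
})

test_that("permutation curve test separates shifted families and bounds p", {
  set.seed(35)
  L <- 40
  A <- matrix(rnorm(8 * L, sd = 0.1), 8, L) + 1
  B <- matrix(rnorm(8 * L, sd = 0.1), 8, L) + 1
  B[, 10:20] <- B[, 10:20] + 2  # shift far beyond within-group SD
  res <- global_permutation_curve_test(A, B, n_perm = 199, seed = 1)
  expect_equal(res$p_global, 1 / 200)
  expect_true(any(res$mask[10:20]))
  expect_true(all(!res$mask[30:40]))

  # observed labeling is part of the null: p can never be below 1/(n_perm+1)
  null_res <- global_permutation_curve_test(A, A + rnorm(8 * L, sd = 0.1),
                                            n_perm = 199, seed = 2)
  expect_gte(null_res$p_global, 1 / 200)
  expect_lte(null_res$p_global, 1)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  set.seed(36)
  A <- matrix(rnorm(60), 5, 12)
  B <- matrix(rnorm(60), 5, 12)
  r1 <- global_permutation_curve_test(A, B, n_perm = 299, seed = 7)
  r2 <- global_permutation_curve_test(A, B, n_perm = 299, seed = 7)
  expect_identical(r1$p_global, r2$p_global)
  expect_identical(r1$mask, r2$mask)
})

test_that("feature group tests: identical groups, Bonferroni, stars", {
  set.seed(37)
  f <- data.frame(refractory = rnorm(20, 1.8, 0.2),
                  peak = rnorm(20, 1.9, 0.2))
  same <- feature_group_tests(rbind(f, f), rep(c("x", "y"), each = 20))
  expect_true(all(abs(same$t) < 1e-12))
  expect_true(all(same$p_corrected == 1))
  expect_true(all(same$stars == ""))

  g <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30), d = rnorm(30))
  g2 <- g; g2$a <- g2$a + 3
  res <- feature_group_tests(rbind(g, g2), rep(c("x", "y"), each = 30))
  expect_equal(res$p_corrected, pmin(1, 4 * res$p_raw))
  expect_equal(res$stars[res$feature == "a"], "***")

  # NaN handling: a feature with too few finite values is skipped
  h <- data.frame(good = rnorm(10), bad = c(NaN, NaN, NaN, NaN, 1,
                                            rnorm(5)))
  h$bad[6:10] <- NaN
  expect_warning(out <- feature_group_tests(rbind(h, h + 1),
                                            rep(c("x", "y"), each = 10)),
                 "skipped")
  expect_false("bad" %in% out$feature)
})

test_that("group comparisons are invariant to within-group row order", {
  set.seed(38)
  f <- data.frame(v = rnorm(40))
  grp <- rep(c("x", "y"), each = 20)
  r1 <- feature_group_tests(f, grp)
  idx <- c(sample(1:20), sample(21:40))
  r2 <- feature_group_tests(f[idx, , drop = FALSE], grp[idx])
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-12)
})
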