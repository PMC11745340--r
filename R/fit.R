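# Maximum-likelihood fitting of the discrete-time point-process GLM.
#
# Counts per bin are modeled as Poisson with mean lambda(t | H_t) * dt and
# log link, the standard discrete-time approximation of the point-process
# likelihood when lambda * dt << 1. The Newton iteration below is exact IRLS
# for the canonical log link (observed information = expected information),
# with step halving on the deviance for robustness.

#' Fit the point-process GLM by maximum likelihood
#'
#' @param design a [build_design_matrix()] result.
#' @param tol convergence tolerance on the Newton step (max absolute change).
#' @param max_iter maximum Newton iterations.
#' @return an object of class `spindle_ppglm` with components `coefficients`
#'   (named; constrained/dropped columns carried as exact zeros), `vcov`
#'   (covariance of the estimated coefficients, from the inverse observed
#'   Fisher information), `log_likelihood` (nats), `deviance`, `n_events`,
#'   `n_bins`, `term_groups`, `spec`, `basis`, `dropped` (columns constrained
#'   to zero and why), `converged`, `iter`.
#' @details Aliased columns are constrained to zero before fitting: stages
#'   with zero occupancy lose their baseline (and interaction) columns with a
#'   warning, and when the full stage-phase interaction block is present
#'   together with the global phase pair, the reference stage's interaction
#'   pair (the occupied stage with the most events) is constrained to zero so
#'   the remaining pairs are offsets from it. Any residual rank deficiency is
#'   resolved by dropping trailing aliased columns, with a warning.
#' @export
fit_point_process_glm <- function(design, tol = 1e-9, max_iter = 50L) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  y <- design$y
  dt <- design$exposure
  if (sum(y) < 1) stop_validation("cannot fit a model with zero events")

  dropped <- character(0)
  groups <- design$term_groups
  # stages with zero occupancy cannot inform their baseline or interactions
  if (!is.null(groups$stage)) {
    occ <- colSums(X[, groups$stage, drop = FALSE]) > 0
    if (any(!occ)) {
      gone_stages <- sub("^stage_", "", groups$stage[!occ])
      warning(sprintf("stage(s) with zero occupancy dropped: %s",
                      paste(gone_stages, collapse = ", ")))
      gone <- c(groups$stage[!occ],
                unlist(lapply(gone_stages, function(s)
                  grep(paste0("^stagephase_", s, "_"), colnames(X), value = TRUE))))
      dropped <- c(dropped, gone)
    }
  }
  # full interaction block + global phase pair is rank deficient by
  # construction: constrain the reference stage (most events) pair to zero
  if (!is.null(groups$stage_phase) && !is.null(groups$phase)) {
    ev_stage <- vapply(STAGES, function(s)
      sum(y[X[, paste0("stage_", s)] > 0]), numeric(1))
    ref <- STAGES[which.max(ev_stage)]
    ref_cols <- paste0("stagephase_", ref, c("_cos", "_sin"))
    dropped <- c(dropped, setdiff(ref_cols, dropped))
    attr(dropped, "reference_stage") <- ref
  }
  keep <- setdiff(colnames(X), dropped)
  Xk <- X[, keep, drop = FALSE]

  # residual rank check on the cross-product (cheap relative to n)
  H0 <- crossprod(Xk)
  qr0 <- qr(H0)
  if (qr0$rank < ncol(Xk)) {
    alias <- colnames(Xk)[sort(qr0$pivot[(qr0$rank + 1L):ncol(Xk)])]
    warning(sprintf("collinear column(s) dropped: %s", paste(alias, collapse = ", ")))
    dropped <- c(dropped, alias)
    keep <- setdiff(keep, alias)
    Xk <- X[, keep, drop = FALSE]
  }

  p <- ncol(Xk)
  off <- log(dt)
  beta <- numeric(p)
  # start every baseline-like column at the overall log rate
  base_cols <- grepl("^stage_|^\\(Intercept\\)", colnames(Xk))
  beta[base_cols] <- log(sum(y) / (length(y) * dt))
  dev_of <- function(eta) {
    mu <- exp(eta)
    2 * sum(mu - y - y * ifelse(y > 0, log(mu / y), 0))
  }
  eta <- drop(Xk %*% beta) + off
  dev <- dev_of(eta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    if (any(!is.finite(mu)))
      stop("intensity overflow during fitting (non-finite mu); ",
           "check covariate scaling", call. = FALSE)
    g <- drop(crossprod(Xk, y - mu))
    H <- crossprod(Xk, Xk * mu)
    # near-empty stages make their block of H vanish as their rate heads to
    # zero (quasi-separation); a small Levenberg ridge keeps the step defined
    # while the flat directions simply stop moving
    ridge <- 0
    step <- NULL
    repeat {
      step <- tryCatch(solve(H + ridge * diag(p), g), error = function(e) NULL)
      if (!is.null(step)) break
      ridge <- if (ridge == 0) 1e-8 * mean(diag(H)) else ridge * 100
      if (!is.finite(ridge) || ridge > 1e12)
        stop("singular information matrix during fitting", call. = FALSE)
    }
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      eta_new <- drop(Xk %*% beta_new) + off
      dev_new <- dev_of(eta_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
      fac <- fac / 2
      if (fac < 1e-10)
        stop("fitting diverged (no descent step found)", call. = FALSE)
    }
    beta <- beta_new
    eta <- eta_new
    moved <- max(abs(fac * step))
    dev_drop <- dev - dev_new
    dev <- dev_new
    if (moved < tol || dev_drop < 1e-12 * (abs(dev) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("maximum Newton iterations reached without full convergence ",
            "(typically a stage with no events); estimates returned")
  mu <- exp(eta)
  H <- crossprod(Xk, Xk * mu)
  vcov <- tryCatch(solve(H), error = function(e) {
    warning("information matrix numerically singular; covariance via pseudo-inverse")
    s <- svd(H)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })
  dimnames(vcov) <- list(keep, keep)
  coef_full <- stats::setNames(numeric(ncol(X)), colnames(X))
  coef_full[keep] <- beta
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  ll_sat <- sum(stats::dpois(y, y, log = TRUE))
  structure(
    list(coefficients = coef_full, estimated = keep, dropped = dropped,
         vcov = vcov, log_likelihood = ll, deviance = 2 * (ll_sat - ll),
         n_events = sum(y), n_bins = length(y), dt_s = dt,
         term_groups = groups, spec = design$spec, basis = design$basis,
         reference_stage = attr(dropped, "reference_stage"),
         converged = converged, iter = it),
    class = "spindle_ppglm"
  )
}

#' @export
print.spindle_ppglm <- function(x, ...) {
  cat(sprintf("<spindle_ppglm> %s | %d events in %d bins (dt = %.3g s)\n",
              paste(names(x$term_groups), collapse = " + "),
              x$n_events, x$n_bins, x$dt_s))
  cat(sprintf("  logLik %.2f, deviance %.2f, %d estimated coefficients%s\n",
              x$log_likelihood, x$deviance, length(x$estimated),
              if (length(x$dropped)) sprintf(" (%d constrained to 0)",
                                             length(x$dropped)) else ""))
  invisible(x)
}

#' @export
coef.spindle_ppglm <- function(object, ...) object$coefficients

#' @export
vcov.spindle_ppglm <- function(object, ...) object$vcov

#' @export
logLik.spindle_ppglm <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$estimated),
            class = "logLik")
}

# Covariance block (with zeros for constrained columns) for arbitrary columns.
vcov_block <- function(model, cols) {
  V <- matrix(0, length(cols), length(cols), dimnames = list(cols, cols))
  est <- intersect(cols, rownames(model$vcov))
  V[est, est] <- model$vcov[est, est]
  V
}

#' Predicted conditional intensity on a covariate grid
#'
#' @param object a fitted `spindle_ppglm`.
#' @param cov a [covariate_series()] (typically the one the model was fitted
#'   on, but any aligned grid works).
#' @param event_times optional event times for the history term.
#' @param ... unused.
#' @return numeric vector of intensities in events per second, one per bin.
#' @export
predict.spindle_ppglm <- function(object, cov, event_times = NULL, ...) {
  design <- build_design_matrix(cov, object$spec, object$basis, event_times)
  if (!identical(colnames(design$X), names(object$coefficients)))
    stop_validation("covariates are inconsistent with the fitted model")
  drop(exp(design$X %*% object$coefficients))
}

#' Likelihood-ratio (chi-squared) test of nested point-process models
#'
#' @param full,reduced fitted `spindle_ppglm` models on the same data, with
#'   the reduced model's terms a subset of the full model's.
#' @return list with `statistic` (deviance difference), `df` (difference in
#'   estimated parameter count) and `p_value` (upper chi-squared tail).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "spindle_ppglm"), inherits(reduced, "spindle_ppglm"))
  if (full$n_bins != reduced$n_bins || full$n_events != reduced$n_events)
    stop_validation("models were not fitted on the same data")
  extra_terms <- setdiff(names(reduced$term_groups), names(full$term_groups))
  if (length(setdiff(extra_terms, "intercept")))
    stop_validation("models are not nested: reduced has term(s) %s absent from full",
                    paste(extra_terms, collapse = ", "))
  df <- length(full$estimated) - length(reduced$estimated)
  if (df < 0) stop_validation("reduced model has more parameters than full")
  stat <- max(reduced$deviance - full$deviance, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Deviance decomposition over a nested model chain
#'
#' Given models ordered from the null to the full model, reports for each
#' step the percentage of the total null-to-full deviance reduction explained
#' by adding that step's factor. Sequential fractions telescope to exactly
#' 100. The step order matters and is recorded in the output; single-factor
#' fractions (each factor added alone to the null) are available via
#' [single_factor_fractions()].
#'
#' @param models named list of fitted `spindle_ppglm` objects ordered null to
#'   full (names label the added factor).
#' @return data.frame of class `deviance_decomposition` with columns `step`,
#'   `factor`, `deviance`, `fraction_pct` (NA for the null row).
#' @export
deviance_fractions <- function(models) {
  stopifnot(is.list(models), length(models) >= 2)
  if (is.null(names(models)) || any(names(models) == ""))
    stop_validation("models must be a named list (names label each added factor)")
  nb <- vapply(models, function(m) m$n_bins, numeric(1))
  ne <- vapply(models, function(m) m$n_events, numeric(1))
  if (length(unique(nb)) > 1 || length(unique(ne)) > 1)
    stop_validation("all models must be fitted on identical data")
  dev <- vapply(models, function(m) m$deviance, numeric(1))
  if (any(diff(dev) > 1e-6 * (abs(dev[1]) + 1)))
    stop_validation("deviance increases along the chain; models are not nested in order")
  total <- dev[1] - dev[length(dev)]
  if (total <= 0) stop_validation("null and full model have equal deviance")
  frac <- c(NA_real_, -diff(dev) / total * 100)
  out <- data.frame(step = seq_along(models) - 1L, factor = names(models),
                    deviance = dev, fraction_pct = frac, row.names = NULL)
  class(out) <- c("deviance_decomposition", "data.frame")
  out
}

#' Single-factor deviance fractions
#'
#' Fraction of the null-to-full deviance reduction captured by each factor
#' added alone to the null model: `(D_null - D_factor) / (D_null - D_full) *
#' 100`.
#'
#' @param null fitted null model.
#' @param factor_models named list of fitted one-factor models.
#' @param full fitted full model.
#' @return data.frame with columns `factor`, `fraction_pct`.
#' @export
single_factor_fractions <- function(null, factor_models, full) {
  total <- null$deviance - full$deviance
  if (total <= 0) stop_validation("null and full model have equal deviance")
  data.frame(
    factor = names(factor_models),
    fraction_pct = vapply(factor_models, function(m)
      (null$deviance - m$deviance) / total * 100, numeric(1)),
    row.names = NULL)
}

#' Synergy index between two model components
#'
#' Per-event log-likelihood gains over the null model are expressed in
#' bits/event: `I_X = (LL_X - LL_null) / (n_events * ln 2)`. The synergy
#' index is `(I_AB - I_A - I_B) / I_AB`: exactly 0 when the two components
#' contribute additively (independent information), negative when they are
#' redundant, positive when jointly more informative than apart.
#'
#' @param null,model_a,model_b,model_ab fitted `spindle_ppglm` models on
#'   identical data; `model_ab` contains the terms of both `model_a` and
#'   `model_b`.
#' @return list with `index` and `gains` (named vector of bits/event for A,
#'   B and AB).
#' @export
synergy_index <- function(null, model_a, model_b, model_ab) {
  nb <- vapply(list(null, model_a, model_b, model_ab),
               function(m) m$n_bins, numeric(1))
  if (length(unique(nb)) > 1)
    stop_validation("all models must be fitted on identical data")
  n_ev <- null$n_events
  gain <- function(m) (m$log_likelihood - null$log_likelihood) / (n_ev * log(2))
  g <- c(A = gain(model_a), B = gain(model_b), AB = gain(model_ab))
  if (g[["AB"]] <= 0)
    stop_validation("joint model provides no information gain; synergy undefined")
  list(index = unname((g[["AB"]] - g[["A"]] - g[["B"]]) / g[["AB"]]), gains = g)
}

#' Time-rescaling goodness of fit (Kolmogorov-Smirnov)
#'
#' Rescales inter-event intervals by the integrated fitted intensity,
#' `tau_j = int lambda dt` between consecutive events, maps them through
#' `z_j = 1 - exp(-tau_j)` and compares against Uniform(0, 1) with a KS test.
#' Under a correctly specified model the z are i.i.d. uniform.
#'
#' @param model a fitted `spindle_ppglm`, or a numeric vector of per-bin
#'   intensities (events/s) for evaluating a known rate.
#' @param train the [event_train()] being assessed.
#' @param cov the [covariate_series()] the intensity lives on (used to
#'   predict when `model` is a fit; only `dt_s` is needed when `model` is a
#'   numeric intensity vector).
#' @return list of class `gof_result`: `ks_statistic`, `n` (number of
#'   rescaled intervals), `pass_05` (TRUE when the statistic is below the
#'   5-percent KS band `1.36 / sqrt(n)`), and the rescaled `z`.
#' @export
time_rescaling_ks <- function(model, train, cov) {
  stopifnot(inherits(train, "event_train"))
  if (length(train$times) < 10)
    stop_validation("need at least 10 events for the time-rescaling KS test")
  lambda <- if (inherits(model, "spindle_ppglm"))
    predict(model, cov, event_times = train$times)
  else as.numeric(model)
  dt <- cov$dt_s
  if (length(lambda) != length(cov$counts))
    stop_validation("intensity length does not match the covariate grid")
  # cumulative integral at bin edges; linear interpolation inside a bin
  # (piecewise-constant lambda) gives the trapezoid evaluation at event times
  edges <- c(0, seq_along(lambda) * dt)
  Lam <- c(0, cumsum(lambda * dt))
  L_at <- stats::approx(edges, Lam, pmin(train$times, max(edges)), rule = 2)$y
  tau <- diff(L_at)
  z <- 1 - exp(-tau)
  ks_uniform(z)
}

#' KS uniformity test for rescaled intervals
#'
#' @param z numeric vector in `[0, 1]`.
#' @return list of class `gof_result` with `ks_statistic`, `n`, `pass_05`, `z`.
#' @export
ks_uniform <- function(z) {
  n <- length(z)
  zs <- sort(z)
  d <- max(pmax(seq_len(n) / n - zs, zs - (seq_len(n) - 1) / n))
  structure(list(ks_statistic = d, n = n, pass_05 = d < 1.36 / sqrt(n), z = z),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> KS = %.4f on %d intervals (5%% band %.4f): %s\n",
              x$ks_statistic, x$n, 1.36 / sqrt(x$n),
              if (x$pass_05) "PASS" else "FAIL"))
  invisible(x)
}
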