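# Population-level comparisons of history curves, their features, and
# preferred phases across recordings and groups.

#' Pearson correlation between two history curves
#'
#' @param curve_a,curve_b [history_modulation_curve()] results (or numeric
#'   vectors) on identical lag grids.
#' @param lag_max restrict to lags `<= lag_max` before correlating (default
#'   15 s, the short-term window); ignored for plain numeric input.
#' @return Pearson correlation coefficient of the modulation values.
#' @export
curve_correlation <- function(curve_a, curve_b, lag_max = 15) {
  if (inherits(curve_a, "history_curve")) {
    if (!inherits(curve_b, "history_curve") ||
        !isTRUE(all.equal(curve_a$lag, curve_b$lag)))
      stop_validation("curves must share an identical lag grid")
    keep <- curve_a$lag <= lag_max
    a <- curve_a$modulation[keep]
    b <- curve_b$modulation[keep]
  } else {
    a <- as.numeric(curve_a)
    b <- as.numeric(curve_b)
    if (length(a) != length(b))
      stop_validation("curves must share an identical lag grid")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_validation("correlation undefined for a zero-variance curve")
  stats::cor(a, b)
}

#' Pairwise correlations within and between subjects
#'
#' Given one curve per (subject, night), returns the intra-subject pool
#' (same subject, different nights) and the inter-subject pool (different
#' subjects, first night each) of pairwise Pearson correlations.
#'
#' @param curves matrix with one row per recording (modulation values on a
#'   common lag grid).
#' @param subject factor/character of subject ids, one per row.
#' @param night integer night index per row.
#' @return list with numeric vectors `intra` and `inter`.
#' @export
correlation_pools <- function(curves, subject, night) {
  stopifnot(nrow(curves) == length(subject), length(subject) == length(night))
  intra <- c()
  for (s in unique(subject)) {
    rows <- which(subject == s)
    if (length(rows) >= 2) {
      prs <- utils::combn(rows, 2)
      intra <- c(intra, apply(prs, 2, function(ij)
        curve_correlation(curves[ij[1], ], curves[ij[2], ])))
    }
  }
  first <- which(night == min(night))
  inter <- c()
  if (length(first) >= 2) {
    prs <- utils::combn(first, 2)
    keep <- subject[prs[1, ]] != subject[prs[2, ]]
    inter <- apply(prs[, keep, drop = FALSE], 2, function(ij)
      curve_correlation(curves[ij[1], ], curves[ij[2], ]))
  }
  list(intra = intra, inter = inter)
}

# Maximum-likelihood-style estimate of the von Mises concentration from the
# mean resultant length (standard piecewise approximation).
kappa_from_rbar <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular one-way comparison of mean angles across groups, with the
#' standard concentration correction factor `1 + 3 / (8 kappa)`. Assumes
#' von Mises samples with common, reasonably high concentration; a warning
#' is issued when the pooled mean resultant length is below 0.45.
#'
#' @param groups list (length >= 2) of numeric vectors of angles in radians,
#'   each with at least 5 observations.
#' @return list with `statistic` (F), `df` (numerator, denominator) and
#'   `p_value`.
#' @export
watson_williams_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, length, integer(1))))
    stop_validation("all groups must be non-empty")
  if (any(vapply(groups, length, integer(1)) < 5))
    stop_validation("each group needs at least 5 angles")
  n_j <- vapply(groups, length, numeric(1))
  N <- sum(n_j)
  p <- length(groups)
  R_j <- vapply(groups, function(a)
    sqrt(sum(cos(a))^2 + sum(sin(a))^2), numeric(1))
  C <- sum(vapply(groups, function(a) sum(cos(a)), numeric(1)))
  S <- sum(vapply(groups, function(a) sum(sin(a)), numeric(1)))
  R <- sqrt(C^2 + S^2)
  rbar <- sum(R_j) / N
  if (rbar < 0.45)
    warning("low concentration (mean resultant length < 0.45); ",
            "Watson-Williams approximation may be unreliable")
  kappa <- kappa_from_rbar(rbar)
  K <- 1 + 3 / (8 * kappa)
  num <- sum(R_j) - R
  den <- N - sum(R_j)
  Fstat <- if (num <= 0) 0 else K * ((N - p) * num) / ((p - 1) * den)
  pval <- stats::pf(Fstat, p - 1, N - p, lower.tail = FALSE)
  list(statistic = Fstat, df = c(p - 1, N - p), p_value = pval)
}

#' Global permutation test between two families of curves
#'
#' Compares two groups of curves with the max-over-lags absolute Welch
#' t-statistic; the null distribution comes from random relabelings of the
#' group memberships. The global p-value is `(1 + #{perm >= observed}) /
#' (n_perm + 1)` (the observed labeling counts as one permutation). The
#' pointwise mask marks lags where the observed |t| exceeds the 95th
#' percentile of the permuted max statistics, controlling the family-wise
#' error over lags at 0.05.
#'
#' @param curves_a,curves_b matrices with one curve per row on a common lag
#'   grid; each group needs at least 2 curves.
#' @param n_perm number of permutations (>= 199).
#' @param seed integer seed for the permutation draws.
#' @param statistic `"max_t"` (default) or `"area"` (area of |t| above its
#'   null 95th pointwise percentile).
#' @return list of class `permutation_curve_result`: `p_global`, `mask`
#'   (logical per lag), `observed_t`, `threshold`, `n_perm`, `seed`.
#' @export
global_permutation_curve_test <- function(curves_a, curves_b, n_perm = 999,
                                          seed = NULL,
                                          statistic = c("max_t", "area")) {
  statistic <- match.arg(statistic)
  curves_a <- as.matrix(curves_a)
  curves_b <- as.matrix(curves_b)
  if (ncol(curves_a) != ncol(curves_b))
    stop_validation("curve families must share a lag grid")
  if (nrow(curves_a) < 2 || nrow(curves_b) < 2)
    stop_validation("each group needs at least 2 curves")
  if (n_perm < 199) stop_validation("n_perm must be at least 199")
  all_c <- rbind(curves_a, curves_b)
  na <- nrow(curves_a)
  n <- nrow(all_c)
  welch_t <- function(idx_a) {
    A <- all_c[idx_a, , drop = FALSE]
    B <- all_c[-idx_a, , drop = FALSE]
    ma <- colMeans(A); mb <- colMeans(B)
    va <- (colSums(A^2) - nrow(A) * ma^2) / ((nrow(A) - 1) * nrow(A))
    vb <- (colSums(B^2) - nrow(B) * mb^2) / ((nrow(B) - 1) * nrow(B))
    abs(ma - mb) / sqrt(va + vb)
  }
  t_obs <- welch_t(seq_len(na))
  with_seed(seed, {
    Tp <- t(vapply(seq_len(n_perm), function(i)
      welch_t(sample.int(n, na)), numeric(ncol(all_c))))
    perm_max <- apply(Tp, 1, max)
    # family-wise 0.05 level over lags via the max-statistic null
    threshold <- stats::quantile(perm_max, 0.95, names = FALSE)
    if (statistic == "max_t") {
      stat_obs <- max(t_obs)
      perm_stat <- perm_max
    } else {
      # area of |t| above the pointwise null 95th percentile
      thr_pt <- apply(Tp, 2, stats::quantile, probs = 0.95, names = FALSE)
      stat_obs <- sum(pmax(t_obs - thr_pt, 0))
      perm_stat <- rowSums(pmax(sweep(Tp, 2, thr_pt), 0))
    }
    p_global <- (1 + sum(perm_stat >= stat_obs)) / (n_perm + 1)
  })
  structure(
    list(p_global = p_global, mask = t_obs > threshold, observed_t = t_obs,
         threshold = threshold, n_perm = n_perm, seed = seed),
    class = "permutation_curve_result")
}

#' Group comparisons of history features with multiplicity correction
#'
#' Welch two-sample t-tests per feature between two groups, Bonferroni
#' corrected across features, with the conventional star annotation
#' (`*`, `**`, `***` for corrected p < 0.05, 0.01, 0.001). NaN feature
#' values are dropped per comparison (with the dropped count reported); a
#' comparison with fewer than 2 values in a group is skipped with a warning.
#'
#' @param features data.frame of numeric feature columns.
#' @param group vector of 2 group labels, one per row of `features`.
#' @param correction multiplicity correction method (default `"bonferroni"`;
#'   any method of [stats::p.adjust()]).
#' @return data.frame of class `group_comparison` with per-feature group
#'   means/SDs, t statistic, raw and corrected p, stars, and dropped counts.
#' @export
feature_group_tests <- function(features, group, correction = "bonferroni") {
  stopifnot(is.data.frame(features), nrow(features) == length(group))
  labs <- unique(group)
  if (length(labs) != 2)
    stop_validation("exactly two groups are required (got %d)", length(labs))
  rows <- lapply(names(features), function(f) {
    x <- features[[f]][group == labs[1]]
    y <- features[[f]][group == labs[2]]
    dropped <- sum(!is.finite(x)) + sum(!is.finite(y))
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("feature '%s' skipped: fewer than 2 finite values in a group", f))
      return(NULL)
    }
    tt <- stats::t.test(x, y)
    data.frame(feature = f, group_a = labs[1], group_b = labs[2],
               mean_a = mean(x), sd_a = stats::sd(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               t = unname(tt$statistic), p_raw = tt$p.value,
               n_dropped = dropped)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_validation("no feature could be compared")
  out$p_corrected <- stats::p.adjust(out$p_raw, method = correction,
                                     n = nrow(out))
  out$stars <- significance_stars(out$p_corrected)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Significance stars
#'
#' @param p numeric vector of p-values.
#' @return `***`, `**`, `*` for p < 0.001, 0.01, 0.05; `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
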