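#' Model specification
#'
#' Switchboard over the terms of the log-linear conditional intensity:
#' sleep stage (one-hot baselines), SO phase (cosine/sine pair), stage-phase
#' interaction, quadratic SO power (used instead of stage when `sop = TRUE`
#' and `stage = FALSE`), SOP-phase interaction, and the spline history term.
#'
#' @param stage include per-stage baseline rates (one-hot, no intercept).
#' @param sop include SO power as `alpha1 * SOP + alpha2 * SOP^2`; when the
#'   stage block is absent an intercept column is added.
#' @param phase include the SO-phase pair `beta1 cos(phi) + beta2 sin(phi)`.
#' @param stage_phase include stage-specific phase pairs (requires `stage`
#'   and `phase`).
#' @param sop_phase include `SOP * cos(phi)`, `SOP * sin(phi)` (requires
#'   `sop` and `phase`), letting the preferred phase drift with sleep depth.
#' @param history one of `"none"`, `"short"` (knots to 15 s) or `"long"`
#'   (knots to 90 s).
#' @param dt_s model bin width in seconds (default 0.1).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(stage = TRUE, sop = FALSE, phase = FALSE,
                       stage_phase = FALSE, sop_phase = FALSE,
                       history = c("none", "short", "long"), dt_s = 0.1) {
  history <- match.arg(history)
  if (stage_phase && !(stage && phase))
    stop_validation("stage_phase requires both stage and phase terms")
  if (sop_phase && !(sop && phase))
    stop_validation("sop_phase requires both sop and phase terms")
  # stage = sop = phase = FALSE, history = "none" is the intercept-only
  # (homogeneous Poisson) null model
  structure(list(stage = stage, sop = sop, phase = phase,
                 stage_phase = stage_phase, sop_phase = sop_phase,
                 history = history, dt_s = dt_s),
            class = "model_spec")
}

#' Parse a compact model-spec token
#'
#' Tokens are `+`-separated combinations of `stage`, `sop`, `phase`,
#' `interaction` (stage-phase), `sopphase`, `history15` and `history90`.
#' Three shorthands exist: `null` (intercept-only homogeneous rate), `full`
#' (`stage+phase+interaction+history15`) and `full90` (the same with the
#' 90-s history).
#'
#' @param token character scalar, e.g. `"stage+phase+interaction+history15"`.
#' @param dt_s bin width passed through to [model_spec()].
#' @return a [model_spec()].
#' @export
parse_spec_token <- function(token, dt_s = 0.1) {
  if (token == "null")
    return(model_spec(stage = FALSE, dt_s = dt_s))
  if (token == "full") token <- "stage+phase+interaction+history15"
  if (token == "full90") token <- "stage+phase+interaction+history90"
  parts <- strsplit(token, "+", fixed = TRUE)[[1]]
  known <- c("stage", "sop", "phase", "interaction", "sopphase",
             "history15", "history90")
  bad <- setdiff(parts, known)
  if (length(bad))
    stop_validation("unknown spec token(s): %s (known: %s)",
                    paste(bad, collapse = ", "), paste(known, collapse = ", "))
  model_spec(stage = "stage" %in% parts, sop = "sop" %in% parts,
             phase = "phase" %in% parts,
             stage_phase = "interaction" %in% parts,
             sop_phase = "sopphase" %in% parts,
             history = if ("history90" %in% parts) "long"
                       else if ("history15" %in% parts) "short" else "none",
             dt_s = dt_s)
}

default_basis_for <- function(spec) {
  switch(spec$history,
         none = NULL,
         short = history_basis(KNOTS_SHORT),
         long = history_basis(KNOTS_LONG))
}

# Lag since the most recent event strictly before each bin start, evaluated
# at bin centers. Bins with no prior event get Inf (all basis columns 0).
lag_since_last_event <- function(times, bin_centers, dt_s) {
  if (!length(times)) return(rep(Inf, length(bin_centers)))
  idx <- findInterval(bin_centers - dt_s / 2 - 1e-12, times)
  lag <- ifelse(idx >= 1L, bin_centers - times[pmax(idx, 1L)], Inf)
  lag
}

#' Build the design matrix for the point-process GLM
#'
#' Columns are grouped by term: the stage block is one-hot over the five
#' stages (rows sum to 1); the phase block is `(cos phi, sin phi)`; the
#' stage-phase block repeats the phase pair per stage (the full block is
#' rank-deficient together with the global pair; the fitter constrains the
#' reference stage's pair to zero); the SOP block is `(SOP, SOP^2)` plus an
#' intercept when the stage block is absent; the SOP-phase block is
#' `(SOP cos phi, SOP sin phi)`; history columns are the cardinal-spline
#' basis evaluated at the lag since the most recent event strictly before
#' each bin start (0 when no event lies within the basis span).
#'
#' @param cov a [covariate_series()].
#' @param spec a [model_spec()].
#' @param basis a [history_basis()]; defaults to the standard short/long
#'   knot layout implied by `spec$history`.
#' @param event_times optional event times used for the history lags;
#'   defaults to the `event_times` attribute of `cov` or, failing that, the
#'   centers of event-containing bins.
#' @return an object of class `design_matrix`: list with the model matrix
#'   `X`, response `y`, `exposure` (bin width), `term_groups` (column names
#'   per term) and the `spec`/`basis` used.
#' @export
build_design_matrix <- function(cov, spec, basis = NULL, event_times = NULL) {
  stopifnot(inherits(cov, "covariate_series"), inherits(spec, "model_spec"))
  n <- length(cov$counts)
  blocks <- list()
  groups <- list()
  if (spec$stage) {
    sb <- sapply(STAGES, function(s) as.numeric(cov$stage == s))
    colnames(sb) <- paste0("stage_", STAGES)
    blocks$stage <- sb
    groups$stage <- colnames(sb)
  } else {
    blocks$intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    groups$intercept <- "(Intercept)"
  }
  if (spec$phase) {
    pb <- cbind(phase_cos = cos(cov$phase), phase_sin = sin(cov$phase))
    blocks$phase <- pb
    groups$phase <- colnames(pb)
  }
  if (spec$stage_phase) {
    ib <- do.call(cbind, lapply(STAGES, function(s) {
      on <- as.numeric(cov$stage == s)
      m <- cbind(on * cos(cov$phase), on * sin(cov$phase))
      colnames(m) <- paste0("stagephase_", s, c("_cos", "_sin"))
      m
    }))
    blocks$stage_phase <- ib
    groups$stage_phase <- colnames(ib)
  }
  if (spec$sop) {
    if (is.null(cov$sop))
      stop_validation("spec includes SOP but covariates carry no SOP series")
    sb <- cbind(sop = cov$sop, sop_sq = cov$sop^2)
    blocks$sop <- sb
    groups$sop <- colnames(sb)
  }
  if (spec$sop_phase) {
    sp <- cbind(sopphase_cos = cov$sop * cos(cov$phase),
                sopphase_sin = cov$sop * sin(cov$phase))
    blocks$sop_phase <- sp
    groups$sop_phase <- colnames(sp)
  }
  if (spec$history != "none") {
    if (is.null(basis)) basis <- default_basis_for(spec)
    if (is.null(event_times)) event_times <- attr(cov, "event_times")
    if (is.null(event_times))
      event_times <- cov$time[cov$counts > 0]
    lag <- lag_since_last_event(event_times, cov$time, cov$dt_s)
    hb <- eval_history_basis(basis, lag)
    colnames(hb) <- sprintf("hist_%02d", seq_len(basis$K))
    blocks$history <- hb
    groups$history <- colnames(hb)
  } else {
    basis <- NULL
  }
  X <- do.call(cbind, blocks)
  structure(list(X = X, y = cov$counts, exposure = cov$dt_s,
                 term_groups = groups, spec = spec, basis = basis),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d bins x %d columns (%s), %d events\n",
              nrow(x$X), ncol(x$X),
              paste(names(x$term_groups), collapse = " + "), sum(x$y)))
  invisible(x)
}
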