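# CSV/JSON persistence. All event, hypnogram, covariate and curve artifacts
# are plain CSV for auditability; fitted models and run manifests are JSON.
# Schemas: events (subject_id, time_s), hypnogram (epoch_index, stage),
# covariates (time_s, phase_rad, sop_norm).

#' Write a recording bundle to a directory
#'
#' @param bundle a `recording_bundle` (see [simulate_night()]) or any list
#'   with `train`, `hypnogram` and optionally `cov`.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest (for provenance).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- bundle$train
  utils::write.csv(data.frame(subject_id = tr$subject_id, time_s = tr$times),
                   file.path(dir, "events.csv"), row.names = FALSE)
  hyp <- bundle$hypnogram
  utils::write.csv(data.frame(epoch_index = seq_along(hyp$stages) - 1L,
                              stage = hyp$stages),
                   file.path(dir, "hypnogram.csv"), row.names = FALSE)
  if (!is.null(bundle$cov)) {
    cv <- bundle$cov
    utils::write.csv(data.frame(time_s = cv$time, phase_rad = cv$phase,
                                sop_norm = if (is.null(cv$sop)) NA else cv$sop),
                     file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  manifest <- list(subject_id = tr$subject_id, duration_s = tr$duration_s,
                   n_events = length(tr$times), epoch_s = hyp$epoch_s,
                   dt_s = if (is.null(bundle$cov)) NA else bundle$cov$dt_s,
                   seed = seed,
                   package_version = as.character(utils::packageVersion("spindlepp")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_validation("%s: missing column(s) %s", file,
                    paste(missing, collapse = ", "))
}

#' Read a recording bundle from a directory
#'
#' Validates schemas on read: events must be sorted, nonnegative and within
#' the recorded duration; hypnogram stages must be one of N1, N2, N3, REM,
#' Wake.
#'
#' @param dir directory written by [write_bundle()].
#' @return a `recording_bundle` (without a scenario).
#' @export
read_bundle <- function(dir) {
  for (f in c("events.csv", "hypnogram.csv", "manifest.json"))
    if (!file.exists(file.path(dir, f)))
      stop_validation("missing file: %s", file.path(dir, f))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  require_columns(ev, c("subject_id", "time_s"), "events.csv")
  if (nrow(ev) && any(ev$time_s < 0))
    stop_validation("events.csv: negative time_s")
  if (nrow(ev) && is.unsorted(ev$time_s, strictly = TRUE))
    stop_validation("events.csv: time_s must be strictly increasing")
  hy <- utils::read.csv(file.path(dir, "hypnogram.csv"))
  require_columns(hy, c("epoch_index", "stage"), "hypnogram.csv")
  bad <- setdiff(unique(hy$stage), STAGES)
  if (length(bad))
    stop_validation("hypnogram.csv: invalid stage label(s) %s",
                    paste(bad, collapse = ", "))
  hyp <- hypnogram(hy$stage, manifest$epoch_s)
  train <- event_train(ev$time_s, manifest$duration_s,
                       if (nrow(ev)) ev$subject_id[1] else manifest$subject_id)
  cov <- NULL
  cov_path <- file.path(dir, "covariates.csv")
  if (file.exists(cov_path)) {
    cv <- utils::read.csv(cov_path)
    require_columns(cv, c("time_s", "phase_rad", "sop_norm"), "covariates.csv")
    dt <- manifest$dt_s
    cov <- covariate_series(dt, stage_at(hyp, cv$time_s), cv$phase_rad,
                            if (all(is.na(cv$sop_norm))) NULL else cv$sop_norm,
                            { cnt <- bin_events(train, dt)
                              length(cnt) <- nrow(cv); cnt[is.na(cnt)] <- 0L
                              cnt })
    attr(cov, "event_times") <- train$times
  }
  structure(list(train = train, hypnogram = hyp, cov = cov,
                 manifest = manifest),
            class = "recording_bundle")
}

#' Serialize a fitted model to JSON
#'
#' @param model a fitted `spindle_ppglm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  obj <- list(
    coefficients = as.list(model$coefficients),
    dropped = model$dropped,
    vcov = model$vcov,
    log_likelihood = model$log_likelihood,
    deviance = model$deviance,
    n_events = model$n_events, n_bins = model$n_bins, dt_s = model$dt_s,
    spec = unclass(model$spec),
    basis = if (is.null(model$basis)) NULL else unclass(model$basis),
    reference_stage = model$reference_stage,
    package_version = as.character(utils::packageVersion("spindlepp")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path file written by [model_to_json()].
#' @return a `spindle_ppglm` (sufficient for prediction and interpretation).
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(obj$coefficients)
  spec <- do.call(model_spec, obj$spec[c("stage", "sop", "phase",
                                         "stage_phase", "sop_phase",
                                         "history", "dt_s")])
  basis <- if (is.null(obj$basis)) NULL
           else history_basis(obj$basis$knots, obj$basis$tension)
  est <- setdiff(names(coefs), obj$dropped)
  V <- obj$vcov
  dimnames(V) <- list(est, est)
  groups <- list()
  grab <- function(pat) grep(pat, names(coefs), value = TRUE)
  if (spec$stage) groups$stage <- grab("^stage_") else
    groups$intercept <- grab("^\\(Intercept\\)")
  if (spec$phase) groups$phase <- grab("^phase_")
  if (spec$stage_phase) groups$stage_phase <- grab("^stagephase_")
  if (spec$sop) groups$sop <- grab("^sop(_sq)?$")
  if (spec$sop_phase) groups$sop_phase <- grab("^sopphase_")
  if (spec$history != "none") groups$history <- grab("^hist_")
  structure(
    list(coefficients = coefs, estimated = est, dropped = obj$dropped,
         vcov = V, log_likelihood = obj$log_likelihood,
         deviance = obj$deviance, n_events = obj$n_events,
         n_bins = obj$n_bins, dt_s = obj$dt_s, term_groups = groups,
         spec = spec, basis = basis, reference_stage = obj$reference_stage,
         converged = TRUE, iter = NA_integer_),
    class = "spindle_ppglm")
}

#' Export a history curve (or features table) as tidy CSV
#'
#' @param x a `history_curve`, `phase_depth_curve` or data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
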