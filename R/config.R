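#' Pipeline configuration
#'
#' All tunable constants of the analysis pipeline with their standard
#' values: 30 Hz resampling, a second-order 6 Hz zero-phase Butterworth
#' low-pass for body streams, 10 Hz synchrony rate, 100 s non-overlapping
#' windows kept only when at least 90% tracked, lag grids of +/-5 s (body)
#' and +/-1 s (face) in 0.1 s steps, a 70/30 train/test partition with
#' five-fold cross-validation, and SVM-RFE down to 23 features.
#'
#' @param resample_rate_hz uniform resampling rate (Hz).
#' @param filter_cutoff_hz,filter_order Butterworth low-pass parameters.
#' @param synchrony_rate_hz rate of the series entering cross-correlation.
#' @param window_s analysis window length (s).
#' @param body_max_lag_s,face_max_lag_s,lag_step_s lag grid (s).
#' @param min_window_valid_fraction validity threshold for keeping a window.
#' @param max_gap_s longest tracking gap bridged by interpolation (s).
#' @param low_variance_threshold variance floor for facial channels.
#' @param n_min_overlap smallest jointly valid overlap for a correlation
#'   cell to count (samples).
#' @param filter_faces also low-pass filter facial streams (default FALSE;
#'   faces are interpolated and downsampled only).
#' @param train_fraction,cv_folds,rfe_target_k classifier protocol.
#' @param max_missing_fraction feature columns missing in more than this
#'   fraction of participants are dropped before imputation.
#' @param group_by_dyad keep both members of a dyad on the same side of
#'   every split (default TRUE; set FALSE for a strict participant-level
#'   partition).
#' @param seed default seed for split randomness.
#' @param rf random-forest hyperparameters: `ntree` 500, `mtry` 20,
#'   `nodesize` 7 (minimum samples per leaf), `max_depth` 10, `bootstrap`
#'   TRUE, `seed` 30.
#' @param mlp multilayer-perceptron hyperparameters: one `hidden` layer of
#'   50 logistic units, L2 penalty `decay` 0.03, `maxit` 200, `seed` 30.
#' @return an object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(resample_rate_hz = 30,
                            filter_cutoff_hz = 6,
                            filter_order = 2,
                            synchrony_rate_hz = 10,
                            window_s = 100,
                            body_max_lag_s = 5,
                            face_max_lag_s = 1,
                            lag_step_s = 0.1,
                            min_window_valid_fraction = 0.9,
                            max_gap_s = 0.2,
                            low_variance_threshold = 1e-4,
                            n_min_overlap = 50,
                            filter_faces = FALSE,
                            train_fraction = 0.7,
                            cv_folds = 5,
                            rfe_target_k = 23,
                            max_missing_fraction = 0.5,
                            group_by_dyad = TRUE,
                            seed = 1L,
                            rf = list(),
                            mlp = list()) {
  cfg <- as.list(environment())
  rf_def <- list(ntree = 500, mtry = 20, nodesize = 7, max_depth = 10,
                 bootstrap = TRUE, seed = 30)
  mlp_def <- list(hidden = 50, decay = 0.03, maxit = 200, seed = 30)
  cfg$rf <- merge_defaults(rf, rf_def, "rf")
  cfg$mlp <- merge_defaults(mlp, mlp_def, "mlp")
  with(cfg, {
    stopifnot(resample_rate_hz > 0, synchrony_rate_hz > 0, window_s > 0,
              body_max_lag_s > 0, face_max_lag_s > 0, lag_step_s > 0,
              max_gap_s > 0, filter_order >= 1, n_min_overlap >= 2,
              min_window_valid_fraction > 0, min_window_valid_fraction <= 1,
              cv_folds >= 2, rfe_target_k >= 1)
    if (train_fraction <= 0 || train_fraction >= 1) {
      stop("train_fraction must lie strictly between 0 and 1")
    }
    if (filter_cutoff_hz >= resample_rate_hz / 2) {
      stop("filter_cutoff_hz must lie below the Nyquist frequency")
    }
    for (ml in c(body_max_lag_s, face_max_lag_s)) {
      if (abs(ml / lag_step_s - round(ml / lag_step_s)) > 1e-9) {
        stop("lag_step_s must divide evenly into the maximum lags")
      }
    }
  })
  structure(cfg, class = "pipeline_config")
}

merge_defaults <- function(user, def, what) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "))
  }
  def[names(user)] <- user
  def
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file take the standard defaults of
#' [pipeline_config()]; unknown keys are an error (no silent typos), as are
#' out-of-range values.  `rf:` and `mlp:` may be nested mappings.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  flat <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-26s %s\n", nm, flat[[nm]]))
  cat(sprintf("  rf:  %s\n", paste(names(x$rf), unlist(x$rf),
                                   sep = "=", collapse = ", ")))
  cat(sprintf("  mlp: %s\n", paste(names(x$mlp), unlist(x$mlp),
                                   sep = "=", collapse = ", ")))
  invisible(x)
}
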