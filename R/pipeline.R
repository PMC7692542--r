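#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates generate -> preprocess -> kinematics -> synchrony ->
#' outcomes -> features -> classify as one reproducible run.  Dyads are
#' generated and reduced to feature vectors one at a time, so cohort size
#' is limited by time, not memory.
#'
#' @param n_dyads number of dyads to simulate.
#' @param synth_cfg a [synth_config()] describing the generative
#'   conditions.
#' @param cfg a [pipeline_config()].
#' @param seed cohort seed (defaults to `synth_cfg$seed`); drives the
#'   generator and the train/test partition.
#' @param out_dir optional directory: the feature table, outcome table,
#'   lag profiles, and run report are written there.
#' @param classify run the classification stage (default TRUE; needs
#'   enough dyads for a stratified partition).
#' @return a `run_report` list: effective configs, per-stage counts,
#'   cohort synchrony summaries and lag profiles, classifier reports,
#'   ground truth, the feature table, and wall-clock seconds per stage.
#' @export
run_pipeline <- function(n_dyads, synth_cfg = synth_config(),
                         cfg = pipeline_config(), seed = synth_cfg$seed,
                         out_dir = NULL, classify = TRUE) {
  t_all <- proc.time()[3]
  truth <- cohort_truth(n_dyads, synth_cfg, seed)
  quest <- generate_questionnaires(truth, synth_cfg, seed)
  outcomes <- outcome_table(quest)

  stage_t <- c()
  t0 <- proc.time()[3]
  feats <- vector("list", 2 * n_dyads)
  ids <- character(2 * n_dyads)
  body_profiles <- face_profiles <- NULL
  n_kept_body <- n_kept_face <- 0L
  dropped_dyads <- character(0)
  for (k in seq_len(n_dyads)) {
    session <- generate_dyad_session(truth$dyads[k, , drop = FALSE],
                                     synth_cfg)
    prep <- lapply(session$participants, preprocess_participant, cfg = cfg)
    sync <- dyad_synchrony_features(prep[[1]], prep[[2]], cfg)
    bp <- attr(sync, "body_profile")
    fp <- attr(sync, "face_profile")
    if (!is.null(bp)) {
      body_profiles <- rbind(body_profiles, bp)
      n_kept_body <- n_kept_body + attr(sync, "n_windows_body")
    }
    if (!is.null(fp)) {
      face_profiles <- rbind(face_profiles, fp)
      n_kept_face <- n_kept_face + attr(sync, "n_windows_face")
    }
    if (is.null(bp) && is.null(fp)) {
      dropped_dyads <- c(dropped_dyads, session$dyad_id)
    }
    for (p in 1:2) {
      i <- (k - 1) * 2 + p
      ids[i] <- session$participants[[p]]$participant_id
      feats[[i]] <- participant_features(session, p, cfg, prep = prep,
                                         sync = sync)
    }
  }
  names(feats) <- ids
  stage_t["features"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  table <- build_feature_table(feats, outcomes, cfg$max_missing_fraction)
  stage_t["table"] <- proc.time()[3] - t0

  cls <- NULL
  if (classify) {
    t0 <- proc.time()[3]
    cls <- classify_attraction(table, cfg, seed)
    stage_t["classify"] <- proc.time()[3] - t0
  }

  lags_body <- seq(-cfg$body_max_lag_s, cfg$body_max_lag_s, cfg$lag_step_s)
  lags_face <- seq(-cfg$face_max_lag_s, cfg$face_max_lag_s, cfg$lag_step_s)
  report <- structure(list(
    n_dyads = n_dyads,
    n_participants = 2L * n_dyads,
    seed = seed,
    synth_config = unclass(synth_cfg),
    pipeline_config = unclass(cfg),
    counts = list(kept_windows_body = n_kept_body,
                  kept_windows_face = n_kept_face,
                  dyads_without_windows = dropped_dyads,
                  dropped_features = attr(table, "dropped_features"),
                  n_imputed_cells = attr(table, "n_imputed")),
    synchrony = list(
      body_mean = mean(table$sync_body_composite_mean, na.rm = TRUE),
      face_mean = mean(table$sync_face_composite_mean, na.rm = TRUE),
      body_profile = data.frame(
        lag_s = lags_body,
        mean_r = if (is.null(body_profiles)) NA_real_
                 else colMeans(body_profiles, na.rm = TRUE)),
      face_profile = data.frame(
        lag_s = lags_face,
        mean_r = if (is.null(face_profiles)) NA_real_
                 else colMeans(face_profiles, na.rm = TRUE))),
    classification = cls,
    feature_table = table,
    truth = truth,
    version = as.character(utils::packageVersion("dyadsync")),
    elapsed_s = c(stage_t, total = proc.time()[3] - t_all)),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d dyads (%d participants), seed %s\n",
              x$n_dyads, x$n_participants, x$seed))
  cat(sprintf("  kept windows: body %d, face %d; dyads without windows: %d\n",
              x$counts$kept_windows_body, x$counts$kept_windows_face,
              length(x$counts$dyads_without_windows)))
  cat(sprintf("  mean synchrony: body %.3f, face %.3f\n",
              x$synchrony$body_mean, x$synchrony$face_mean))
  if (!is.null(x$classification)) {
    for (nm in c("rf", "mlp")) {
      m <- x$classification[[nm]]
      cat(sprintf("  %-3s cv %.2f%% (SD %.2f%%), test %.2f%% (baseline %.2f%%)\n",
                  nm, 100 * m$cv$mean, 100 * m$cv$sd,
                  100 * m$report$accuracy,
                  100 * m$report$majority_baseline))
    }
  }
  invisible(x)
}

# write the run artifacts: tables as CSV, report as JSON, summary markdown
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ft <- report$feature_table
  utils::write.csv(ft, file.path(out_dir, "feature_table.csv"),
                   row.names = FALSE)
  utils::write.csv(
    ft[, c("participant_id", "dyad_id", "attraction", "impression_accuracy",
           "affective_valence", "gender")],
    file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(report$synchrony$body_profile,
                   file.path(out_dir, "body_lag_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(report$synchrony$face_profile,
                   file.path(out_dir, "face_lag_profile.csv"),
                   row.names = FALSE)
  dict <- feature_dictionary()
  dict <- dict[dict$name %in% attr(ft, "feature_names"), , drop = FALSE]
  jsonlite::write_json(dict, file.path(out_dir, "feature_dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(report$classification)) {
    for (nm in c("rf", "mlp")) {
      cm <- report$classification[[nm]]$report$confusion
      utils::write.csv(as.data.frame.matrix(cm),
                       file.path(out_dir, paste0("confusion_", nm, ".csv")))
    }
  }
  json <- report[c("n_dyads", "n_participants", "seed", "synth_config",
                   "pipeline_config", "counts", "version", "elapsed_s")]
  json$synchrony <- report$synchrony[c("body_mean", "face_mean")]
  if (!is.null(report$classification)) {
    json$classifiers <- lapply(report$classification[c("rf", "mlp")],
                               function(m) list(
      cv_mean = m$cv$mean, cv_sd = m$cv$sd,
      test_accuracy = m$report$accuracy,
      majority_baseline = m$report$majority_baseline,
      sensitivity = m$report$sensitivity,
      specificity = m$report$specificity,
      confusion = m$report$confusion))
    json$selected_features <- report$classification$selected
  }
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report_render(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render a run report as markdown
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
report_render <- function(report) {
  lines <- c(
    "# dyadsync run report",
    "",
    sprintf("- dyads: %d (%d participants), seed %s, package %s",
            report$n_dyads, report$n_participants, report$seed,
            report$version),
    sprintf("- kept windows: body %d, face %d",
            report$counts$kept_windows_body,
            report$counts$kept_windows_face),
    sprintf("- dyads without any kept window: %s",
            if (length(report$counts$dyads_without_windows) == 0) "none"
            else paste(report$counts$dyads_without_windows, collapse = ", ")),
    sprintf("- dropped feature columns: %d; imputed cells: %d",
            length(report$counts$dropped_features),
            report$counts$n_imputed_cells),
    "",
    "## Synchrony (summaries: mean, absolute mean, nonnegative mean,",
    "maximum, absolute maximum of the windowed cross-correlations)",
    "",
    sprintf("- cohort mean body synchrony (mean r): %.4f",
            report$synchrony$body_mean),
    sprintf("- cohort mean face synchrony (mean r): %.4f",
            report$synchrony$face_mean),
    sprintf("- body lag profile: %d lags; face lag profile: %d lags",
            nrow(report$synchrony$body_profile),
            nrow(report$synchrony$face_profile)))
  if (!is.null(report$classification)) {
    lines <- c(lines, "", "## Classification (high vs. low attraction)", "")
    for (nm in c("rf", "mlp")) {
      m <- report$classification[[nm]]
      lines <- c(lines, sprintf(
        "- %s: CV accuracy %.2f%% (SD %.2f%%), test accuracy %.2f%%, majority baseline %.2f%%, sensitivity %.2f, specificity %.2f",
        ifelse(nm == "rf", "random forest", "MLP"),
        100 * m$cv$mean, 100 * m$cv$sd, 100 * m$report$accuracy,
        100 * m$report$majority_baseline, m$report$sensitivity,
        m$report$specificity))
    }
    lines <- c(lines, sprintf("- selected features (%d): %s",
                              length(report$classification$selected),
                              paste(report$classification$selected,
                                    collapse = ", ")))
  }
  lines
}
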