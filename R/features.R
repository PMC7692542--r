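#' Six-statistic block of a scalar series
#'
#' The per-channel summary used throughout the candidate feature layer:
#' mean, standard deviation, mean of the gradient, standard deviation of
#' the gradient, maximum of the gradient, and maximum of the second
#' gradient.  Gradients are first differences scaled to per-second units;
#' the maxima are of the signed values.  Statistics run over valid frames
#' only (a gradient entry needs both bracketing frames valid); fewer than
#' 3 valid frames yields all six missing.
#'
#' @param values numeric vector.
#' @param valid logical mask (default all valid).
#' @param rate_hz sampling rate used to scale differences.
#' @return named numeric vector
#'   `c(mean, sd, grad_mean, grad_sd, grad_max, grad2_max)`.
#' @export
stat_block <- function(values, valid = NULL, rate_hz = 30) {
  if (is.null(valid)) valid <- !is.na(values)
  valid <- valid & !is.na(values)
  out <- c(mean = NA_real_, sd = NA_real_, grad_mean = NA_real_,
           grad_sd = NA_real_, grad_max = NA_real_, grad2_max = NA_real_)
  if (sum(valid) < 3) return(out)
  v <- values
  g <- diff(v) * rate_hz
  gv <- valid[-length(valid)] & valid[-1]
  g2 <- diff(g) * rate_hz
  g2v <- gv[-length(gv)] & gv[-1]
  out["mean"] <- mean(v[valid])
  out["sd"] <- stats::sd(v[valid])
  if (any(gv)) {
    out["grad_mean"] <- mean(g[gv])
    out["grad_sd"] <- if (sum(gv) > 1) stats::sd(g[gv]) else 0
    out["grad_max"] <- max(g[gv])
  }
  if (any(g2v)) out["grad2_max"] <- max(g2[g2v])
  out
}

# column standard deviations without matrixStats
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(NA_real_, ncol(m)))
  sqrt(pmax(colSums(m * m) - n * colMeans(m)^2, 0) / (n - 1))
}

# stat_block() across all columns of a matrix at once (frame-level mask)
matrix_stat_block <- function(M, valid, rate_hz) {
  six <- c("mean", "sd", "grad_mean", "grad_sd", "grad_max", "grad2_max")
  out <- matrix(NA_real_, 6, ncol(M), dimnames = list(six, colnames(M)))
  if (sum(valid) < 3) return(out)
  V <- M[valid, , drop = FALSE]
  out["mean", ] <- colMeans(V)
  out["sd", ] <- col_sds(V)
  n <- nrow(M)
  G <- diff(M) * rate_hz
  gv <- valid[-n] & valid[-1]
  if (any(gv)) {
    Gv <- G[gv, , drop = FALSE]
    out["grad_mean", ] <- colMeans(Gv)
    out["grad_sd", ] <- if (nrow(Gv) > 1) col_sds(Gv) else 0
    out["grad_max", ] <- apply(Gv, 2, max)
  }
  g2v <- gv[-length(gv)] & gv[-1]
  if (any(g2v)) {
    G2 <- diff(G)[g2v, , drop = FALSE] * rate_hz
    out["grad2_max", ] <- apply(G2, 2, max)
  }
  out
}

# statistic suffixes of the synchrony summaries
sync_stats <- c("mean", "absmean", "nonnegmean", "max", "absmax")

summary_to_vec <- function(s) {
  c(mean = s$mean_r, absmean = s$abs_mean_r, nonnegmean = s$nonneg_mean_r,
    max = s$max_r, absmax = s$abs_max_r)
}

# five summaries straight from a windows x lags slice of an r array
slice_summaries <- function(r) {
  cells <- r[!is.na(r)]
  if (!length(cells)) {
    return(c(mean = NA_real_, absmean = NA_real_, nonnegmean = NA_real_,
             max = NA_real_, absmax = NA_real_))
  }
  nonneg <- cells[cells >= 0]
  c(mean = mean(cells), absmean = mean(abs(cells)),
    nonnegmean = if (length(nonneg)) mean(nonneg) else NA_real_,
    max = max(cells), absmax = cells[which.max(abs(cells))])
}

#' Deterministic enumeration of the candidate feature names
#'
#' The fixed, documented naming of every candidate feature, grouped in
#' blocks: (a) five synchrony summaries for the composite body extent,
#' each of the 17 per-joint extent series, each of the 10 joint angles,
#' the composite facial-movement series, and each of the 52 unmerged
#' facial channels; (b) six statistics per joint coordinate; (c) mean/SD
#' of per-joint displacement per 0.1 s; (d) four statistics per joint
#' angle; (e) head-rotation statistics; (f) mean/SD per merged blendshape
#' item; (g) gaze statistics; (h) tracking-validity summaries per stream;
#' (i) gender.
#'
#' @return character vector of feature names;
#'   `n_candidate_features()` returns its length (878).
#' @export
candidate_feature_names <- function() {
  joints <- upper_body_joints()
  angles <- names(default_angle_defs())
  faces <- blendshape_channels()
  items <- names(blendshape_pairs())
  six <- c("mean", "sd", "grad_mean", "grad_sd", "grad_max", "grad2_max")
  c(
    paste0("sync_body_composite_", sync_stats),
    as.vector(t(outer(paste0("sync_joint_", joints, "_"), sync_stats,
                      paste0))),
    as.vector(t(outer(paste0("sync_angle_", angles, "_"), sync_stats,
                      paste0))),
    paste0("sync_face_composite_", sync_stats),
    as.vector(t(outer(paste0("sync_face_", faces, "_"), sync_stats,
                      paste0))),
    as.vector(t(outer(paste0("pos_", skeleton_colnames(), "_"), six,
                      paste0))),
    as.vector(t(outer(paste0("disp10_", joints, "_"), c("mean", "sd"),
                      paste0))),
    as.vector(t(outer(paste0("angle_", angles, "_"),
                      c("mean", "sd", "absgrad_mean", "absgrad_sd"),
                      paste0))),
    as.vector(t(outer(paste0("head_", c("pitch", "yaw", "roll"), "_"),
                      c("mean", "sd", "grad_mean", "grad_sd"), paste0))),
    as.vector(t(outer(paste0("blend_", items, "_"), c("mean", "sd"),
                      paste0))),
    as.vector(t(outer(paste0("gaze_", c("gx", "gy"), "_"), c("mean", "sd"),
                      paste0))),
    as.vector(t(outer(c("skeleton", "blendshapes", "head_pose", "gaze"),
                      c("valid_pct", "max_miss_run"),
                      function(a, b) paste0("track_", a, "_", b)))),
    "gender_female"
  )
}

#' @rdname candidate_feature_names
#' @export
n_candidate_features <- function() length(candidate_feature_names())

#' Data dictionary of the candidate features
#'
#' One row per candidate feature: its block, units, and a short
#' definition.  Written as a JSON sidecar next to the feature table by
#' [run_pipeline()].
#'
#' @return data frame with columns `name`, `block`, `units`,
#'   `definition`.
#' @export
feature_dictionary <- function() {
  nms <- candidate_feature_names()
  block <- rep("synchrony", length(nms))
  block[grepl("^pos_", nms)] <- "joint_coordinate_stats"
  block[grepl("^disp10_", nms)] <- "displacement_per_0.1s"
  block[grepl("^angle_", nms)] <- "joint_angle_stats"
  block[grepl("^head_", nms)] <- "head_rotation_stats"
  block[grepl("^blend_", nms)] <- "blendshape_stats"
  block[grepl("^gaze_", nms)] <- "gaze_stats"
  block[grepl("^track_", nms)] <- "tracking_validity"
  block[nms == "gender_female"] <- "demographics"
  units <- rep("correlation", length(nms))
  units[grepl("^pos_", nms)] <- "m (or m/s, m/s^2 for gradients)"
  units[grepl("^disp10_", nms)] <- "m per 0.1 s"
  units[grepl("^angle_", nms)] <- "degrees (deg/s for gradients)"
  units[grepl("^head_", nms)] <- "degrees (deg/s for gradients)"
  units[grepl("^blend_", nms)] <- "unitless [0, 1]"
  units[grepl("^gaze_", nms)] <- "normalized screen coordinates"
  units[grepl("_valid_pct$", nms)] <- "percent"
  units[grepl("_max_miss_run$", nms)] <- "frames"
  units[nms == "gender_female"] <- "indicator"
  defn <- rep("windowed lagged cross-correlation summary", length(nms))
  defn[grepl("^pos_", nms)] <-
    "statistic of a filtered 30 Hz joint coordinate"
  defn[grepl("^disp10_", nms)] <-
    "per-joint Euclidean displacement between consecutive 10 Hz frames"
  defn[grepl("^angle_", nms)] <- "statistic of a 30 Hz joint-angle series"
  defn[grepl("^head_", nms)] <- "statistic of 30 Hz head rotation"
  defn[grepl("^blend_", nms)] <-
    "statistic of a merged 30 Hz blendshape item"
  defn[grepl("^gaze_", nms)] <- "statistic of 30 Hz point of gaze"
  defn[grepl("^track_", nms)] <-
    "tracking-validity summary on the uniform grid"
  defn[nms == "gender_female"] <- "1 if the dyad is female, 0 if male"
  data.frame(name = nms, block = block, units = units, definition = defn,
             stringsAsFactors = FALSE)
}

# per-participant preprocessed bundle reused by features and synchrony
preprocess_participant <- function(rec, cfg) {
  sk <- interpolate_uniform(rec$skeleton$timestamps, rec$skeleton$values,
                            cfg$resample_rate_hz, rec$skeleton$valid,
                            cfg$max_gap_s)
  skf <- butterworth_zero_phase(sk, cfg$filter_cutoff_hz, cfg$filter_order)
  face <- interpolate_uniform(rec$blendshapes$timestamps,
                              rec$blendshapes$values, cfg$resample_rate_hz,
                              rec$blendshapes$valid, cfg$max_gap_s)
  if (isTRUE(cfg$filter_faces)) {
    face <- butterworth_zero_phase(face, cfg$filter_cutoff_hz,
                                   cfg$filter_order)
  }
  head <- interpolate_uniform(rec$head_pose$timestamps, rec$head_pose$values,
                              cfg$resample_rate_hz, rec$head_pose$valid,
                              cfg$max_gap_s)
  gaze <- interpolate_uniform(rec$gaze$timestamps, rec$gaze$values,
                              cfg$resample_rate_hz, rec$gaze$valid,
                              cfg$max_gap_s)
  ext <- frame_displacement(skf)
  ang <- joint_angles(skf)
  list(skel = skf, face = face, head = head, gaze = gaze,
       extent = ext, angles = ang,
       extent10 = downsample_series(ext, cfg$synchrony_rate_hz),
       angles10 = downsample_series(ang, cfg$synchrony_rate_hz),
       skel10 = downsample_series(skf, cfg$synchrony_rate_hz),
       face10 = downsample_series(face, cfg$synchrony_rate_hz))
}

# face composite series (merged, variance-screened) at 30 Hz
face_composite_series <- function(face, cfg) {
  merged <- merge_blend_pairs(face)
  v <- merged$values[merged$valid, , drop = FALSE]
  nv <- nrow(v)
  vars <- if (nv > 1) {
    (colSums(v * v) - nv * colMeans(v)^2) / (nv - 1)
  } else rep(0, ncol(v))
  keep <- which(vars >= cfg$low_variance_threshold)
  comp <- if (length(keep)) rowMeans(merged$values[, keep, drop = FALSE])
          else rowMeans(merged$values)
  uniform_series(comp, merged$rate_hz, merged$start, merged$valid)
}

#' Synchrony feature block of one dyad
#'
#' Computes the five synchrony summaries for the composite body extent,
#' every per-joint extent series, every joint angle (lag grid +/-5 s), the
#' composite facial-movement series and every unmerged facial channel
#' (lag grid +/-1 s), all at the synchrony rate over the dyad's combined
#' kept windows.  Both members of a dyad share this block.
#'
#' @param prep_a,prep_b preprocessed participant bundles (internal).
#' @param cfg a [pipeline_config()].
#' @return named numeric vector of the 405 synchrony features.
#' @keywords internal
dyad_synchrony_features <- function(prep_a, prep_b, cfg) {
  joints <- upper_body_joints()
  angles <- names(default_angle_defs())
  faces <- blendshape_channels()
  out <- rep(NA_real_, 5 * (2 + length(joints) + length(angles) +
                              length(faces)))
  names(out) <- grep("^sync_", candidate_feature_names(), value = TRUE)

  n10 <- min(nrow(prep_a$extent10$values), nrow(prep_b$extent10$values))
  idx <- seq_len(n10)
  comp_a <- uniform_series(prep_a$extent10$values[idx, "composite",
                                                  drop = FALSE],
                           cfg$synchrony_rate_hz, 0,
                           prep_a$extent10$valid[idx])
  comp_b <- uniform_series(prep_b$extent10$values[idx, "composite",
                                                  drop = FALSE],
                           cfg$synchrony_rate_hz, 0,
                           prep_b$extent10$valid[idx])
  plan_body <- combine_window_plans(
    plan_windows(comp_a, cfg$window_s, cfg$min_window_valid_fraction),
    plan_windows(comp_b, cfg$window_s, cfg$min_window_valid_fraction))
  if (any(plan_body$keep)) {
    Xa <- prep_a$extent10$values[idx, c(joints, "composite"), drop = FALSE]
    Xb <- prep_b$extent10$values[idx, c(joints, "composite"), drop = FALSE]
    eng <- wcc_engine(Xa, Xb, prep_a$extent10$valid[idx],
                      prep_b$extent10$valid[idx], plan_body,
                      cfg$synchrony_rate_hz, cfg$body_max_lag_s,
                      cfg$lag_step_s, cfg$n_min_overlap)
    for (j in seq_along(joints)) {
      out[paste0("sync_joint_", joints[j], "_", sync_stats)] <-
        slice_summaries(eng$r[, , j, drop = FALSE])
    }
    rb <- eng$r[, , length(joints) + 1, drop = FALSE]
    dim(rb) <- dim(rb)[1:2]
    out[paste0("sync_body_composite_", sync_stats)] <- slice_summaries(rb)
    attr(out, "body_profile") <- colMeans(rb, na.rm = TRUE)
    attr(out, "n_windows_body") <- nrow(rb)
    na10 <- min(nrow(prep_a$angles10$values), nrow(prep_b$angles10$values),
                n10)
    ai <- seq_len(na10)
    eng_a <- wcc_engine(prep_a$angles10$values[ai, , drop = FALSE],
                        prep_b$angles10$values[ai, , drop = FALSE],
                        prep_a$angles10$valid[ai], prep_b$angles10$valid[ai],
                        plan_body, cfg$synchrony_rate_hz, cfg$body_max_lag_s,
                        cfg$lag_step_s, cfg$n_min_overlap)
    for (k in seq_along(angles)) {
      out[paste0("sync_angle_", angles[k], "_", sync_stats)] <-
        slice_summaries(eng_a$r[, , k, drop = FALSE])
    }
  }

  fcomp_a <- downsample_series(face_composite_series(prep_a$face, cfg),
                               cfg$synchrony_rate_hz)
  fcomp_b <- downsample_series(face_composite_series(prep_b$face, cfg),
                               cfg$synchrony_rate_hz)
  nf <- min(nrow(fcomp_a$values), nrow(fcomp_b$values),
            nrow(prep_a$face10$values), nrow(prep_b$face10$values))
  fi <- seq_len(nf)
  plan_face <- combine_window_plans(
    plan_windows(fcomp_a, cfg$window_s, cfg$min_window_valid_fraction),
    plan_windows(fcomp_b, cfg$window_s, cfg$min_window_valid_fraction))
  if (any(plan_face$keep)) {
    Xa <- cbind(prep_a$face10$values[fi, faces, drop = FALSE],
                composite = fcomp_a$values[fi, 1])
    Xb <- cbind(prep_b$face10$values[fi, faces, drop = FALSE],
                composite = fcomp_b$values[fi, 1])
    eng_f <- wcc_engine(Xa, Xb, prep_a$face10$valid[fi] & fcomp_a$valid[fi],
                        prep_b$face10$valid[fi] & fcomp_b$valid[fi],
                        plan_face, cfg$synchrony_rate_hz, cfg$face_max_lag_s,
                        cfg$lag_step_s, cfg$n_min_overlap)
    for (j in seq_along(faces)) {
      out[paste0("sync_face_", faces[j], "_", sync_stats)] <-
        slice_summaries(eng_f$r[, , j, drop = FALSE])
    }
    rf <- eng_f$r[, , length(faces) + 1, drop = FALSE]
    dim(rf) <- dim(rf)[1:2]
    out[paste0("sync_face_composite_", sync_stats)] <- slice_summaries(rf)
    attr(out, "face_profile") <- colMeans(rf, na.rm = TRUE)
    attr(out, "n_windows_face") <- nrow(rf)
  }
  out
}

#' Candidate feature vector of one participant
#'
#' Assembles the full named candidate feature vector for one member of a
#' dyad session (see [candidate_feature_names()] for the enumeration).
#' Both members share the synchrony block; everything else is
#' participant-specific.  Features whose inputs are unavailable (e.g.
#' synchrony of a constant channel, or a stream with too few valid frames)
#' are `NA`, never silently zero.
#'
#' @param session a [dyad_session].
#' @param index 1 or 2: which participant.
#' @param cfg a [pipeline_config()].
#' @param prep,sync optional precomputed bundles (used by the cohort
#'   runner to avoid recomputation).
#' @return named numeric vector of length `n_candidate_features()`.
#' @export
participant_features <- function(session, index, cfg = pipeline_config(),
                                 prep = NULL, sync = NULL) {
  stopifnot(inherits(session, "dyad_session"), index %in% 1:2)
  if (is.null(prep)) {
    prep <- lapply(session$participants, preprocess_participant, cfg = cfg)
  }
  if (is.null(sync)) {
    sync <- dyad_synchrony_features(prep[[1]], prep[[2]], cfg)
  }
  me <- prep[[index]]
  rate <- cfg$resample_rate_hz
  out <- rep(NA_real_, n_candidate_features())
  names(out) <- candidate_feature_names()
  out[names(sync)] <- sync

  # (b) six statistics per joint coordinate (filtered 30 Hz positions)
  sb <- matrix_stat_block(me$skel$values, me$skel$valid, rate)
  for (s in rownames(sb)) {
    out[paste0("pos_", skeleton_colnames(), "_", s)] <- sb[s, ]
  }
  # (c) displacement per 0.1 s from the 10 Hz positions
  disp10 <- frame_displacement(me$skel10)
  dv <- disp10$values[disp10$valid, upper_body_joints(), drop = FALSE]
  if (nrow(dv) >= 2) {
    out[paste0("disp10_", upper_body_joints(), "_mean")] <- colMeans(dv)
    out[paste0("disp10_", upper_body_joints(), "_sd")] <- col_sds(dv)
  }
  # (d) angle statistics
  for (a in names(default_angle_defs())) {
    v <- me$angles$values[, a]
    ok <- me$angles$valid & !is.na(v)
    if (sum(ok) >= 3) {
      g <- abs(diff(v) * rate)
      gok <- ok[-length(ok)] & ok[-1]
      out[paste0("angle_", a, c("_mean", "_sd", "_absgrad_mean",
                                "_absgrad_sd"))] <-
        c(mean(v[ok]), stats::sd(v[ok]), mean(g[gok]), stats::sd(g[gok]))
    }
  }
  # (e) head rotation
  for (h in c("pitch", "yaw", "roll")) {
    sb <- stat_block(me$head$values[, h], me$head$valid, rate)
    out[paste0("head_", h, c("_mean", "_sd", "_grad_mean", "_grad_sd"))] <-
      sb[c("mean", "sd", "grad_mean", "grad_sd")]
  }
  # (f) merged blendshape items
  merged <- merge_blend_pairs(me$face)
  mv <- merged$values[merged$valid, , drop = FALSE]
  if (nrow(mv) >= 2) {
    items <- names(blendshape_pairs())
    out[paste0("blend_", items, "_mean")] <- colMeans(mv[, items, drop = FALSE])
    out[paste0("blend_", items, "_sd")] <- col_sds(mv[, items, drop = FALSE])
  }
  # (g) gaze
  gv <- me$gaze$values[me$gaze$valid, , drop = FALSE]
  if (nrow(gv) >= 2) {
    for (g in c("gx", "gy")) {
      out[paste0("gaze_", g, c("_mean", "_sd"))] <-
        c(mean(gv[, g]), stats::sd(gv[, g]))
    }
  }
  # (h) tracking validity per stream (on the uniform 30 Hz grid)
  streams <- list(skeleton = me$skel, blendshapes = me$face,
                  head_pose = me$head, gaze = me$gaze)
  for (nm in names(streams)) {
    v <- streams[[nm]]$valid
    out[paste0("track_", nm, "_valid_pct")] <- 100 * mean(v)
    out[paste0("track_", nm, "_max_miss_run")] <- max_run(!v)
  }
  # (i) gender
  out["gender_female"] <- as.numeric(session$gender == "F")
  out
}

#' Assemble the cohort feature table
#'
#' Binds per-participant feature vectors into a participants x features
#' table aligned with the outcome records.  Columns missing in more than
#' `max_missing_fraction` of participants are dropped (and listed);
#' remaining missing cells are median-imputed (and counted).  Non-missing
#' cells are never altered.
#'
#' @param feature_list named list (participant id -> feature vector).
#' @param outcomes data frame from [outcome_table()].
#' @param max_missing_fraction drop threshold (default 0.5).
#' @return a `feature_table`: data frame with `participant_id`, `dyad_id`,
#'   outcome columns, and one column per retained feature; attributes
#'   `dropped_features` and `n_imputed`.
#' @export
build_feature_table <- function(feature_list, outcomes,
                                max_missing_fraction = 0.5) {
  ids <- names(feature_list)
  if (anyDuplicated(ids)) {
    stop("duplicate participant id: ", ids[duplicated(ids)][1])
  }
  stopifnot(setequal(ids, outcomes$participant_id))
  X <- do.call(rbind, feature_list[outcomes$participant_id])
  miss_frac <- colMeans(is.na(X))
  dropped <- colnames(X)[miss_frac > max_missing_fraction]
  X <- X[, miss_frac <= max_missing_fraction, drop = FALSE]
  n_imp <- 0L
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) {
      X[na, j] <- stats::median(X[, j], na.rm = TRUE)
      n_imp <- n_imp + sum(na)
    }
  }
  out <- cbind(outcomes, as.data.frame(X, check.names = FALSE))
  attr(out, "feature_names") <- colnames(X)
  attr(out, "dropped_features") <- dropped
  attr(out, "n_imputed") <- n_imp
  class(out) <- c("feature_table", "data.frame")
  out
}
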