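#' Per-frame joint displacement (extent of bodily movement)
#'
#' For each joint, the Euclidean distance between its positions in
#' consecutive frames of a uniform 30 Hz skeleton series -- the
#' between-frame (0.033 s) travel in meters.  The composite channel is the
#' mean across the 17 joints; a composite frame is valid only when the
#' frame and its predecessor are valid for all joints, so the composite's
#' scale never shifts with partial joint dropout.
#'
#' @param skel a [uniform_series] whose columns are the 51
#'   `Joint_x/y/z` skeleton channels.
#' @return a [uniform_series] (same rate) with one displacement channel per
#'   joint plus a `composite` channel; the first frame is invalid.
#' @export
frame_displacement <- function(skel) {
  stopifnot(is_uniform_series(skel))
  if (!identical(colnames(skel$values), skeleton_colnames())) {
    stop("expected the 51 skeleton channels in canonical order")
  }
  joints <- upper_body_joints()
  n <- nrow(skel$values)
  d <- diff(skel$values)                       # (n-1) x 51
  sq <- d^2
  disp <- matrix(NA_real_, n, length(joints) + 1,
                 dimnames = list(NULL, c(joints, "composite")))
  for (j in seq_along(joints)) {
    cols <- (j - 1) * 3 + 1:3
    dj <- sqrt(rowSums(sq[, cols, drop = FALSE]))
    dj[dj < 1e-9] <- 0   # sub-nanometer motion is numerical residue
    disp[-1, j] <- dj
  }
  disp[-1, "composite"] <- rowMeans(disp[-1, seq_along(joints), drop = FALSE])
  ok <- c(FALSE, skel$valid[-1] & skel$valid[-n])
  disp[!ok, ] <- NA_real_
  uniform_series(disp, skel$rate_hz, skel$start, ok)
}

#' Mean extent of bodily movement
#'
#' Per-joint mean displacement over valid frames, and the composite score:
#' the mean of the 17 per-joint means.
#'
#' @param skel a skeleton [uniform_series] at 30 Hz, or an extent series
#'   already computed by [frame_displacement()].
#' @return list with `composite` (scalar, m per frame interval) and
#'   `per_joint` (named numeric vector).
#' @export
body_extent <- function(skel) {
  ext <- if (identical(colnames(skel$values), skeleton_colnames())) {
    frame_displacement(skel)
  } else skel
  if (!any(ext$valid)) stop("no valid frames to average")
  joints <- upper_body_joints()
  per_joint <- colMeans(ext$values[ext$valid, joints, drop = FALSE])
  list(composite = mean(per_joint), per_joint = per_joint)
}

#' Merge left/right blendshape channels into single items
#'
#' Facial expressions with a left and a right component are averaged into a
#' single item; unpaired channels pass through.
#'
#' @param face a [uniform_series] over the 52 blendshape channels.
#' @return a [uniform_series] over the 34 merged items.
#' @export
merge_blend_pairs <- function(face) {
  stopifnot(is_uniform_series(face))
  pairs <- blendshape_pairs()
  out <- matrix(NA_real_, nrow(face$values), length(pairs),
                dimnames = list(NULL, names(pairs)))
  for (nm in names(pairs)) {
    out[, nm] <- rowMeans(face$values[, pairs[[nm]], drop = FALSE])
  }
  uniform_series(out, face$rate_hz, face$start, face$valid)
}

#' Mean extent of facial movement
#'
#' Left/right channel pairs are first averaged into single items; items
#' whose variance over the interaction falls below
#' `low_variance_threshold` are excluded (low-variance channels mostly
#' carry spurious tracking values); the remaining items are averaged over
#' valid frames (deviation from the neutral position, which is 0), and the
#' composite is the mean of the surviving per-item means.
#'
#' @param face a [uniform_series] over the 52 blendshape channels (or
#'   already-merged items).
#' @param low_variance_threshold variance floor for a merged item to be
#'   retained (default 1e-4).
#' @return list with `composite`, `per_channel` (named vector over
#'   surviving items), and `excluded` (names of dropped items).
#' @export
face_extent <- function(face, low_variance_threshold = 1e-4) {
  merged <- if (identical(colnames(face$values), blendshape_channels())) {
    merge_blend_pairs(face)
  } else face
  if (!any(merged$valid)) stop("no valid frames to average")
  v <- merged$values[merged$valid, , drop = FALSE]
  vars <- apply(v, 2, stats::var)
  keep <- vars >= low_variance_threshold
  if (!any(keep)) {
    stop("all facial channels fall below the variance threshold (",
         low_variance_threshold, ")")
  }
  per_channel <- colMeans(v[, keep, drop = FALSE])
  list(composite = mean(per_channel), per_channel = per_channel,
       excluded = colnames(v)[!keep])
}

#' Joint angles from skeleton positions
#'
#' For each ordered joint triple (A, B, C) the angle at the middle joint B
#' between bone vectors B->A and B->C, in degrees.  A frame's angle is
#' invalid if the frame itself is invalid or either bone vector has zero
#' length.
#'
#' @param skel a skeleton [uniform_series] (51 canonical channels).
#' @param angle_defs named list of ordered joint triples; defaults to
#'   [default_angle_defs()] (10 angles).
#' @return a [uniform_series] with one channel per angle, values in
#'   \[0, 180\] degrees.
#' @export
joint_angles <- function(skel, angle_defs = default_angle_defs()) {
  stopifnot(is_uniform_series(skel))
  n <- nrow(skel$values)
  out <- matrix(NA_real_, n, length(angle_defs),
                dimnames = list(NULL, names(angle_defs)))
  jcols <- function(j) skel$values[, paste(j, c("x", "y", "z"), sep = "_"),
                                   drop = FALSE]
  for (nm in names(angle_defs)) {
    tri <- angle_defs[[nm]]
    u <- jcols(tri[1]) - jcols(tri[2])
    v <- jcols(tri[3]) - jcols(tri[2])
    nu <- sqrt(rowSums(u^2))
    nv <- sqrt(rowSums(v^2))
    cosang <- rowSums(u * v) / (nu * nv)
    ang <- acos(clamp(cosang, -1, 1)) * 180 / pi
    ang[nu == 0 | nv == 0] <- NA_real_
    out[, nm] <- ang
  }
  out[!skel$valid, ] <- NA_real_
  uniform_series(out, skel$rate_hz, skel$start, skel$valid)
}
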