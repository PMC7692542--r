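#' Raw tracked streams for one participant
#'
#' Bundles the four raw streams recorded for one person during a session:
#' skeletal joint positions (17 upper-body joints x 3 coordinates, meters),
#' facial blendshape activations (52 channels in \[0, 1\]), head rotation
#' (pitch/yaw/roll, degrees), and 2-D point of gaze (normalized screen
#' coordinates).  Each stream carries its own timestamps (seconds from
#' session start, strictly increasing) and per-frame validity flags.
#'
#' `validate_recording()` checks the structural invariants and flags --
#' rather than drops -- frames violating value bounds (blendshapes outside
#' \[0, 1\], joint coordinates of magnitude 10 m or more): downstream
#' window-validity screening is the mechanism for handling bad data.
#'
#' @param participant_id character id.
#' @param skeleton,blendshapes,head_pose,gaze each a list with elements
#'   `timestamps` (numeric), `values` (numeric matrix with named columns:
#'   `Joint_x/y/z` for the skeleton, blendshape names, `pitch/yaw/roll`,
#'   `gx/gy`), and optionally `valid` (logical per frame).
#' @return an object of class `participant_recording`.
#' @export
participant_recording <- function(participant_id, skeleton, blendshapes,
                                  head_pose, gaze) {
  rec <- structure(
    list(participant_id = participant_id,
         skeleton = as_stream(skeleton),
         blendshapes = as_stream(blendshapes),
         head_pose = as_stream(head_pose),
         gaze = as_stream(gaze)),
    class = "participant_recording"
  )
  validate_recording(rec)
}

as_stream <- function(s) {
  stopifnot(is.list(s), !is.null(s$timestamps), !is.null(s$values))
  if (is.vector(s$values)) s$values <- matrix(s$values, ncol = 1)
  if (is.null(s$valid)) s$valid <- rep(TRUE, length(s$timestamps))
  stopifnot(length(s$timestamps) == nrow(s$values),
            length(s$valid) == nrow(s$values))
  s[c("timestamps", "values", "valid")]
}

#' @rdname participant_recording
#' @param rec a `participant_recording`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "participant_recording"))
  for (nm in c("skeleton", "blendshapes", "head_pose", "gaze")) {
    ts <- rec[[nm]]$timestamps
    if (length(ts) > 1 && any(diff(ts) <= 0)) {
      stop("non-monotone timestamps in stream '", nm, "' at row ",
           which(diff(ts) <= 0)[1] + 1)
    }
  }
  sk_cols <- skeleton_colnames()
  if (!identical(colnames(rec$skeleton$values), sk_cols)) {
    miss <- setdiff(sk_cols, colnames(rec$skeleton$values))
    extra <- setdiff(colnames(rec$skeleton$values), sk_cols)
    stop("skeleton columns mismatch; missing: [",
         paste(miss, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  }
  if (!identical(colnames(rec$blendshapes$values), blendshape_channels())) {
    stop("blendshape columns must be the 52 channel names in canonical order")
  }
  # bound violations become invalid frames, not errors
  sk <- rec$skeleton$values
  bad_sk <- rowSums(is.na(sk) | abs(sk) >= 10) > 0
  if (any(bad_sk & rec$skeleton$valid)) {
    warning(sum(bad_sk & rec$skeleton$valid),
            " skeleton frame(s) flagged invalid (NA or |coordinate| >= 10 m)")
    rec$skeleton$valid <- rec$skeleton$valid & !bad_sk
  } else {
    rec$skeleton$valid <- rec$skeleton$valid & !bad_sk
  }
  bs <- rec$blendshapes$values
  bad_bs <- rowSums(is.na(bs) | bs < 0 | bs > 1) > 0
  if (any(bad_bs & rec$blendshapes$valid)) {
    warning(sum(bad_bs & rec$blendshapes$valid),
            " blendshape frame(s) flagged invalid (value outside [0, 1])")
  }
  rec$blendshapes$valid <- rec$blendshapes$valid & !bad_bs
  rec$head_pose$valid <- rec$head_pose$valid &
    rowSums(is.na(rec$head_pose$values)) == 0
  rec$gaze$valid <- rec$gaze$valid & rowSums(is.na(rec$gaze$values)) == 0
  rec
}

#' @export
print.participant_recording <- function(x, ...) {
  cat(sprintf("<participant_recording> %s\n", x$participant_id))
  for (nm in c("skeleton", "blendshapes", "head_pose", "gaze")) {
    cat(sprintf("  %-12s %5d frames, %3d channels, %.1f%% valid\n", nm,
                nrow(x[[nm]]$values), ncol(x[[nm]]$values),
                100 * mean(x[[nm]]$valid)))
  }
  invisible(x)
}

#' One recorded dyadic session
#'
#' Exactly two [participant_recording]s plus the cell of the 2x2
#' (body visible x face visible) design the dyad was assigned to, the
#' dyad's gender (held constant within dyad), and task order.
#'
#' @param dyad_id character id.
#' @param participants list of exactly two [participant_recording]s.
#' @param body_visible,face_visible logical condition flags.
#' @param gender `"F"` or `"M"`.
#' @param task_order `"visual_first"` or `"semantic_first"`.
#' @return an object of class `dyad_session`.
#' @export
dyad_session <- function(dyad_id, participants, body_visible, face_visible,
                         gender = c("F", "M"),
                         task_order = c("visual_first", "semantic_first")) {
  gender <- match.arg(gender)
  task_order <- match.arg(task_order)
  stopifnot(length(participants) == 2,
            all(vapply(participants, inherits, logical(1),
                       "participant_recording")),
            is.logical(body_visible), is.logical(face_visible))
  structure(
    list(dyad_id = dyad_id, participants = participants,
         condition = list(body_visible = body_visible,
                          face_visible = face_visible),
         gender = gender, task_order = task_order),
    class = "dyad_session"
  )
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session> %s (body %s, face %s, %s, %s)\n", x$dyad_id,
              x$condition$body_visible, x$condition$face_visible,
              x$gender, x$task_order))
  invisible(x)
}
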