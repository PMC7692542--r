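#' Read and write recording streams
#'
#' On-disk layout: one directory per participant holding one wide CSV per
#' stream (`skeleton.csv`, `blendshapes.csv`, `head_pose.csv`, `gaze.csv`),
#' each with columns `timestamp`, `valid`, then one column per channel
#' (`{Joint}_{x|y|z}` for the skeleton, blendshape names verbatim,
#' `pitch/yaw/roll`, `gx/gy`).  `NA` values serialize as empty cells and
#' read back as invalid frames.  A session is a JSON manifest naming the
#' two participant directories plus the dyad metadata.
#'
#' `read_recording()` validates the header against the documented schema
#' (missing or extra columns are an error naming them) and timestamps for
#' monotonicity (error with the first offending row); frames violating
#' value bounds are flagged invalid, not dropped.
#'
#' @param path CSV file of one stream.
#' @param schema one of `"skeleton"`, `"blendshapes"`, `"head_pose"`,
#'   `"gaze"`.
#' @return `read_recording()` returns a stream list (`timestamps`,
#'   `values`, `valid`); `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, schema = c("skeleton", "blendshapes",
                                            "head_pose", "gaze")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- c("timestamp", "valid", stream_channels(schema))
  miss <- setdiff(want, names(df))
  extra <- setdiff(names(df), want)
  if (length(miss) || length(extra)) {
    stop("schema mismatch for '", schema, "'; missing: [",
         paste(miss, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  }
  df <- df[, want, drop = FALSE]
  ts <- df$timestamp
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    stop("non-monotone timestamps at row ", which(diff(ts) <= 0)[1] + 1)
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  list(timestamps = ts, values = vals, valid = as.logical(df$valid))
}

stream_channels <- function(schema) {
  switch(schema,
         skeleton = skeleton_colnames(),
         blendshapes = blendshape_channels(),
         head_pose = c("pitch", "yaw", "roll"),
         gaze = c("gx", "gy"))
}

#' @rdname read_recording
#' @param stream a stream list (`timestamps`, `values`, `valid`).
#' @export
write_recording <- function(stream, path) {
  stream <- as_stream(stream)
  df <- data.frame(timestamp = stream$timestamps,
                   valid = stream$valid,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(stream$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a full dyad session
#'
#' `write_session()` creates one directory per participant with the four
#' stream CSVs and a `session.json` manifest holding the dyad metadata and
#' file names.  `read_session()` reconstructs the [dyad_session], flagging
#' (not dropping) frames that violate value bounds.
#'
#' @param session a [dyad_session].
#' @param dir output directory (created if needed).
#' @return `write_session()` the manifest path invisibly; `read_session()`
#'   a [dyad_session].
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "dyad_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdirs <- character(2)
  for (p in 1:2) {
    rec <- session$participants[[p]]
    pdirs[p] <- rec$participant_id
    pd <- file.path(dir, pdirs[p])
    dir.create(pd, showWarnings = FALSE)
    for (nm in c("skeleton", "blendshapes", "head_pose", "gaze")) {
      write_recording(rec[[nm]], file.path(pd, paste0(nm, ".csv")))
    }
  }
  manifest <- list(dyad_id = session$dyad_id,
                   condition = session$condition,
                   gender = session$gender,
                   task_order = session$task_order,
                   participants = as.list(pdirs))
  path <- file.path(dir, "session.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "session.json"),
                                  simplifyVector = TRUE)
  recs <- lapply(manifest$participants, function(pid) {
    pd <- file.path(dir, pid)
    participant_recording(
      participant_id = pid,
      skeleton = read_recording(file.path(pd, "skeleton.csv"), "skeleton"),
      blendshapes = read_recording(file.path(pd, "blendshapes.csv"),
                                   "blendshapes"),
      head_pose = read_recording(file.path(pd, "head_pose.csv"), "head_pose"),
      gaze = read_recording(file.path(pd, "gaze.csv"), "gaze"))
  })
  dyad_session(manifest$dyad_id, recs,
               body_visible = manifest$condition$body_visible,
               face_visible = manifest$condition$face_visible,
               gender = manifest$gender, task_order = manifest$task_order)
}

#' Write / read questionnaire records
#'
#' Wide CSV: one row per participant with `att1..att8` (attraction items),
#' `bfi_self1..15`, `bfi_obs1..15` ("Cannot make judgment" as empty cell),
#' `pos_pct`, `neg_pct`, `gender`.
#'
#' @param records a `questionnaire_records` data frame (see
#'   [generate_questionnaires()]).
#' @param path CSV path.
#' @return the path / the records, invisibly for writers.
#' @export
write_questionnaires <- function(records, path) {
  wide <- data.frame(participant_id = records$participant_id,
                     dyad_id = records$dyad_id,
                     gender = records$gender,
                     pos_pct = records$pos_pct,
                     neg_pct = records$neg_pct)
  att <- do.call(rbind, records$attraction_items)
  colnames(att) <- paste0("att", 1:8)
  bs <- do.call(rbind, records$bfi_self)
  colnames(bs) <- paste0("bfi_self", 1:15)
  bo <- do.call(rbind, records$bfi_observer)
  colnames(bo) <- paste0("bfi_obs", 1:15)
  utils::write.csv(cbind(wide, att, bs, bo), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_questionnaires
#' @export
read_questionnaires <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("participant_id", "dyad_id", "gender", "pos_pct", "neg_pct",
            paste0("att", 1:8), paste0("bfi_self", 1:15),
            paste0("bfi_obs", 1:15))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("questionnaire CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- df[, c("participant_id", "dyad_id", "gender", "pos_pct", "neg_pct")]
  out$attraction_items <- lapply(seq_len(nrow(df)), function(i)
    as.integer(df[i, paste0("att", 1:8)]))
  out$bfi_self <- lapply(seq_len(nrow(df)), function(i)
    as.integer(df[i, paste0("bfi_self", 1:15)]))
  out$bfi_observer <- lapply(seq_len(nrow(df)), function(i)
    as.integer(df[i, paste0("bfi_obs", 1:15)]))
  class(out) <- c("questionnaire_records", "data.frame")
  out
}
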