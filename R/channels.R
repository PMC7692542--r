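#' Tracked channel vocabularies
#'
#' The upper-body joint set, facial blendshape set, and joint-angle
#' definitions used throughout the package.  Seventeen upper-body joints are
#' retained from the depth sensor's 25-joint skeleton (lower-body joints are
#' dropped because markerless tracking is unreliable there), and 52 facial
#' blendshape channels in \[0, 1\] encode deviation of a facial region from
#' its neutral position.
#'
#' @return `upper_body_joints()` returns a character vector of 17 joint
#'   names; `blendshape_channels()` a character vector of 52 channel names;
#'   `blendshape_pairs()` a named list mapping each merged item name to the
#'   one or two raw channels it averages; `default_angle_defs()` a named
#'   list of 10 ordered joint triples (the angle is measured at the middle
#'   joint).
#' @examples
#' length(upper_body_joints())   # 17
#' length(blendshape_channels()) # 52
#' @export
upper_body_joints <- function() {
  c("SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft", "HandTipLeft",
    "ThumbLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HandTipRight", "ThumbRight")
}

#' @rdname upper_body_joints
#' @export
blendshape_channels <- function() {
  c("browDownLeft", "browDownRight", "browInnerUp",
    "browOuterUpLeft", "browOuterUpRight",
    "cheekPuff", "cheekSquintLeft", "cheekSquintRight",
    "eyeBlinkLeft", "eyeBlinkRight",
    "eyeLookDownLeft", "eyeLookDownRight",
    "eyeLookInLeft", "eyeLookInRight",
    "eyeLookOutLeft", "eyeLookOutRight",
    "eyeLookUpLeft", "eyeLookUpRight",
    "eyeSquintLeft", "eyeSquintRight",
    "eyeWideLeft", "eyeWideRight",
    "jawForward", "jawLeft", "jawOpen", "jawRight",
    "mouthClose",
    "mouthDimpleLeft", "mouthDimpleRight",
    "mouthFrownLeft", "mouthFrownRight",
    "mouthFunnel", "mouthLeft",
    "mouthLowerDownLeft", "mouthLowerDownRight",
    "mouthPressLeft", "mouthPressRight",
    "mouthPucker", "mouthRight",
    "mouthRollLower", "mouthRollUpper",
    "mouthShrugLower", "mouthShrugUpper",
    "mouthSmileLeft", "mouthSmileRight",
    "mouthStretchLeft", "mouthStretchRight",
    "mouthUpperUpLeft", "mouthUpperUpRight",
    "noseSneerLeft", "noseSneerRight",
    "tongueOut")
}

#' @rdname upper_body_joints
#' @export
blendshape_pairs <- function() {
  ch <- blendshape_channels()
  # channels that are left/right variants of the same expression are merged;
  # jawLeft/jawRight and mouthLeft/mouthRight are directional movements, not
  # mirrored variants, and stay separate
  paired_stems <- c("browDown", "browOuterUp", "cheekSquint", "eyeBlink",
                    "eyeLookDown", "eyeLookIn", "eyeLookOut", "eyeLookUp",
                    "eyeSquint", "eyeWide", "mouthDimple", "mouthFrown",
                    "mouthLowerDown", "mouthPress", "mouthSmile",
                    "mouthStretch", "mouthUpperUp", "noseSneer")
  out <- list()
  for (stem in paired_stems) {
    out[[stem]] <- paste0(stem, c("Left", "Right"))
  }
  singles <- setdiff(ch, unlist(out))
  for (s in singles) out[[s]] <- s
  # stable order: paired stems first is arbitrary; sort by name for determinism
  out[order(names(out))]
}

#' @rdname upper_body_joints
#' @export
default_angle_defs <- function() {
  list(
    ElbowLeftAngle     = c("ShoulderLeft", "ElbowLeft", "WristLeft"),
    ElbowRightAngle    = c("ShoulderRight", "ElbowRight", "WristRight"),
    ShoulderLeftAngle  = c("SpineShoulder", "ShoulderLeft", "ElbowLeft"),
    ShoulderRightAngle = c("SpineShoulder", "ShoulderRight", "ElbowRight"),
    WristLeftAngle     = c("ElbowLeft", "WristLeft", "HandLeft"),
    WristRightAngle    = c("ElbowRight", "WristRight", "HandRight"),
    HandLeftAngle      = c("WristLeft", "HandLeft", "HandTipLeft"),
    HandRightAngle     = c("WristRight", "HandRight", "HandTipRight"),
    NeckAngle          = c("Head", "Neck", "SpineShoulder"),
    SpineAngle         = c("Neck", "SpineShoulder", "SpineMid")
  )
}

# Rest positions (meters, sensor-centered: +x right from the sensor's view,
# +y up, +z from sensor toward participant standing ~2.05 m away).
default_skeleton_template <- function() {
  z <- 2.05
  m <- rbind(
    SpineBase     = c(0.00, 1.00, z),
    SpineMid      = c(0.00, 1.25, z),
    SpineShoulder = c(0.00, 1.45, z),
    Neck          = c(0.00, 1.52, z),
    Head          = c(0.00, 1.68, z),
    ShoulderLeft  = c(-0.19, 1.44, z),
    ElbowLeft     = c(-0.26, 1.18, z),
    WristLeft     = c(-0.28, 0.95, z - 0.05),
    HandLeft      = c(-0.28, 0.90, z - 0.08),
    HandTipLeft   = c(-0.28, 0.85, z - 0.10),
    ThumbLeft     = c(-0.24, 0.89, z - 0.09),
    ShoulderRight = c(0.19, 1.44, z),
    ElbowRight    = c(0.26, 1.18, z),
    WristRight    = c(0.28, 0.95, z - 0.05),
    HandRight     = c(0.28, 0.90, z - 0.08),
    HandTipRight  = c(0.28, 0.85, z - 0.10),
    ThumbRight    = c(0.24, 0.89, z - 0.09)
  )
  colnames(m) <- c("x", "y", "z")
  m[upper_body_joints(), , drop = FALSE]
}

# column names of the wide skeleton matrix: Joint_x, Joint_y, Joint_z
skeleton_colnames <- function(joints = upper_body_joints()) {
  as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = "_")))
}
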