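# Signed angle (degrees) from vector u to vector v in image coordinates
# (x right, y down), via atan2 of the 2-D cross and dot products. Stable
# for vertical segments, where slope-ratio formulas divide by zero; on
# non-degenerate input it agrees with the arctangent-of-slope-difference
# formulation up to sign conventions.
vector_angle <- function(ux, uy, vx, vy) {
  atan2(ux * vy - uy * vx, ux * vx + uy * vy) * 180 / pi
}

dir_sign <- function(direction) {
  switch(direction, left_to_right = 1, right_to_left = -1,
         stop("sagittal direction required, got ", direction))
}

#' Sagittal hip angle series
#'
#' Angle between the thigh axis (hip to knee keypoint) and the trunk axis
#' (midshoulder KP1 to midhip KP8), equivalently 90 degrees minus the
#' angle between the thigh and the perpendicular-to-trunk axis. Flexion
#' (knee anterior to the trunk line) is positive. `NA` where any of the
#' four keypoints is missing.
#'
#' @param seq A `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @param direction Sagittal walking direction (fixes the anterior sign).
#' @return Numeric vector of degrees per frame.
#' @export
hip_angle <- function(seq, side, direction) {
  k <- kp_side(side)
  ux <- kp_x(seq, KP_MIDHIP) - kp_x(seq, KP_NECK)
  uy <- kp_y(seq, KP_MIDHIP) - kp_y(seq, KP_NECK)
  vx <- kp_x(seq, k$knee) - kp_x(seq, k$hip)
  vy <- kp_y(seq, k$knee) - kp_y(seq, k$hip)
  -dir_sign(direction) * vector_angle(ux, uy, vx, vy)
}

#' Sagittal knee angle series
#'
#' Angle between the thigh axis (hip to knee) and the shank axis (knee to
#' ankle); zero when collinear, flexion (ankle posterior to the extended
#' thigh line) positive.
#'
#' @inheritParams hip_angle
#' @return Numeric vector of degrees per frame.
#' @export
knee_angle <- function(seq, side, direction) {
  k <- kp_side(side)
  ux <- kp_x(seq, k$knee) - kp_x(seq, k$hip)
  uy <- kp_y(seq, k$knee) - kp_y(seq, k$hip)
  vx <- kp_x(seq, k$ankle) - kp_x(seq, k$knee)
  vy <- kp_y(seq, k$ankle) - kp_y(seq, k$knee)
  dir_sign(direction) * vector_angle(ux, uy, vx, vy)
}

# Midtoe: mean of the big- and small-toe keypoints of one side.
midtoe_xy <- function(seq, side) {
  k <- kp_side(side)
  list(x = (kp_x(seq, k$bigtoe) + kp_x(seq, k$smalltoe)) / 2,
       y = (kp_y(seq, k$bigtoe) + kp_y(seq, k$smalltoe)) / 2)
}

#' Sagittal ankle angle series
#'
#' Angle between the foot axis (heel to midtoe, where midtoe is the mean
#' of the big- and small-toe keypoints) and the shank axis (knee to
#' ankle). The neutral reading is 90 degrees (foot perpendicular to the
#' shank); dorsiflexion increases the value, so
#' `dorsiflexion = ankle_angle - 90`.
#'
#' @inheritParams hip_angle
#' @return Numeric vector of degrees per frame.
#' @export
ankle_angle <- function(seq, side, direction) {
  k <- kp_side(side)
  mt <- midtoe_xy(seq, side)
  ux <- kp_x(seq, k$ankle) - kp_x(seq, k$knee)
  uy <- kp_y(seq, k$ankle) - kp_y(seq, k$knee)
  vx <- mt$x - kp_x(seq, k$heel)
  vy <- mt$y - kp_y(seq, k$heel)
  -dir_sign(direction) * vector_angle(ux, uy, vx, vy)
}

#' Dorsiflexion angle relative to neutral
#'
#' Convenience wrapper: [ankle_angle()] minus the 90-degree neutral
#' reading, so positive values are dorsiflexion and negative values
#' plantarflexion.
#'
#' @inheritParams hip_angle
#' @return Numeric vector of degrees per frame.
#' @export
dorsiflexion_angle <- function(seq, side, direction) {
  ankle_angle(seq, side, direction) - 90
}

#' Signed angle between a segment and an image axis
#'
#' For the x-axis the result is in `(-90, 90]` and positive when the
#' forward endpoint `b` sits higher in the image (smaller y) than `a`.
#' For the y-axis the segment is first oriented to point upward in the
#' image and the result is positive when that upward direction tilts
#' toward larger x; callers apply walking-direction or stance-side sign
#' flips on top of this base convention.
#'
#' @param ax,ay,bx,by Segment endpoint coordinates (vectors allowed).
#' @param axis `"image_x"` or `"image_y"`.
#' @return Signed degrees; `NA` propagates. Coincident endpoints abort
#'   for scalar input and yield `NA` frames in vector input.
#' @export
segment_axis_angle <- function(ax, ay, bx, by, axis = c("image_x", "image_y")) {
  axis <- match.arg(axis)
  dx <- bx - ax; dy <- by - ay
  degenerate <- !is.na(dx) & !is.na(dy) & dx == 0 & dy == 0
  if (any(degenerate)) {
    if (length(dx) == 1) stop("undefined angle: coincident segment endpoints")
    dx[degenerate] <- NA_real_; dy[degenerate] <- NA_real_
  }
  if (axis == "image_x") {
    atan2(-dy, abs(dx)) * 180 / pi
  } else {
    flip <- !is.na(dy) & dy > 0 # orient upward (decreasing y)
    dx[flip] <- -dx[flip]; dy[flip] <- -dy[flip]
    atan2(dx, -dy) * 180 / pi
  }
}

#' Foot-axis angle versus the image x-axis
#'
#' Heel-to-midtoe line against the horizontal; positive when the toes are
#' higher in the image than the heel. This is the measurement behind the
#' initial-contact rule.
#'
#' @param seq A `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of degrees per frame.
#' @export
foot_axis_angle <- function(seq, side) {
  k <- kp_side(side)
  mt <- midtoe_xy(seq, side)
  segment_axis_angle(kp_x(seq, k$heel), kp_y(seq, k$heel), mt$x, mt$y,
                     axis = "image_x")
}

#' Sagittal trunk angle versus vertical
#'
#' Midhip-to-midshoulder line against the image y-axis, signed so forward
#' lean (toward the walking direction) is positive.
#'
#' @param seq A `pose_sequence`.
#' @param direction Sagittal walking direction.
#' @return Numeric vector of degrees per frame.
#' @export
trunk_sagittal_angle <- function(seq, direction) {
  a <- segment_axis_angle(kp_x(seq, KP_MIDHIP), kp_y(seq, KP_MIDHIP),
                          kp_x(seq, KP_NECK), kp_y(seq, KP_NECK),
                          axis = "image_y")
  dir_sign(direction) * a
}

#' Coronal trunk angle versus vertical
#'
#' Trunk line against the image y-axis in the base convention (positive
#' tilt toward larger x); the lateral-trunk-shift scorer re-signs it
#' toward the stance side.
#'
#' @param seq A `pose_sequence`.
#' @return Numeric vector of degrees per frame.
#' @export
trunk_coronal_angle <- function(seq) {
  segment_axis_angle(kp_x(seq, KP_MIDHIP), kp_y(seq, KP_MIDHIP),
                     kp_x(seq, KP_NECK), kp_y(seq, KP_NECK),
                     axis = "image_y")
}

#' Hip-line angle versus an image axis
#'
#' Line connecting the right (KP9) and left (KP12) hip keypoints. Against
#' the x-axis this is the pelvic-obliquity surrogate (coronal view);
#' against the y-axis it is the pelvic-rotation surrogate (sagittal
#' view), which is numerically fragile because the hip keypoints nearly
#' coincide in that projection.
#'
#' @param seq A `pose_sequence`.
#' @param axis `"image_x"` or `"image_y"`.
#' @return Numeric vector of degrees per frame.
#' @export
hip_line_angle <- function(seq, axis = "image_x") {
  segment_axis_angle(kp_x(seq, KP_RHIP), kp_y(seq, KP_RHIP),
                     kp_x(seq, KP_LHIP), kp_y(seq, KP_LHIP), axis = axis)
}

#' Hindfoot line angle versus vertical
#'
#' Ankle-to-heel line against the image y-axis (coronal view), base sign
#' convention as in [segment_axis_angle()]; the hindfoot scorer maps it
#' to valgus (lateral lean) positive per side.
#'
#' @param seq A `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of degrees per frame.
#' @export
hindfoot_angle <- function(seq, side) {
  k <- kp_side(side)
  segment_axis_angle(kp_x(seq, k$heel), kp_y(seq, k$heel),
                     kp_x(seq, k$ankle), kp_y(seq, k$ankle), axis = "image_y")
}

#' Coronal foot-rotation angle versus vertical
#'
#' Heel-to-midtoe line against the image y-axis, signed so external
#' rotation (toes pointing away from the body midline, taken as the
#' midhip x) is positive.
#'
#' @param seq A `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of degrees per frame.
#' @export
foot_rotation_angle <- function(seq, side) {
  k <- kp_side(side)
  mt <- midtoe_xy(seq, side)
  hx <- kp_x(seq, k$heel); hy <- kp_y(seq, k$heel)
  a <- segment_axis_angle(hx, hy, mt$x, mt$y, axis = "image_y")
  outward <- sign(hx - kp_x(seq, KP_MIDHIP)) # which image side this foot is on
  tilt <- sign(mt$x - hx)
  s <- ifelse(outward == 0 | tilt == 0, 1, ifelse(outward == tilt, 1, -1))
  abs(a) * ifelse(s >= 0, 1, -1) * ifelse(is.na(a), NA, 1)
}

#' Coronal ankle angle (knee-progression surrogate)
#'
#' Angle between the foot line (heel to midtoe) and the shank line (knee
#' to ankle) as they appear in the coronal projection, folded to
#' `(-90, 90]`. Internal knee rotation twists the foot line relative to
#' the shank line in the image, which this angle senses.
#'
#' @param seq A `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @return Numeric vector of degrees per frame.
#' @export
coronal_ankle_angle <- function(seq, side) {
  k <- kp_side(side)
  mt <- midtoe_xy(seq, side)
  ux <- kp_x(seq, k$ankle) - kp_x(seq, k$knee)
  uy <- kp_y(seq, k$ankle) - kp_y(seq, k$knee)
  vx <- mt$x - kp_x(seq, k$heel)
  vy <- mt$y - kp_y(seq, k$heel)
  a <- vector_angle(ux, uy, vx, vy)
  # line-vs-line angle: fold to (-90, 90]
  a <- ifelse(a > 90, a - 180, a)
  ifelse(a <= -90, a + 180, a)
}

#' All angle series needed for scoring
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param view `"sagittal"` or `"coronal"`.
#' @param direction Walking direction label.
#' @return Named list of per-frame series, per side where applicable.
#' @export
angle_series <- function(seq, view, direction) {
  out <- list()
  if (view == "sagittal") {
    for (side in c("left", "right")) {
      out[[side]] <- list(
        hip = hip_angle(seq, side, direction),
        knee = knee_angle(seq, side, direction),
        dorsiflexion = dorsiflexion_angle(seq, side, direction),
        foot_axis = foot_axis_angle(seq, side))
    }
    out$trunk <- trunk_sagittal_angle(seq, direction)
    out$hip_line_y <- hip_line_angle(seq, axis = "image_y")
  } else {
    for (side in c("left", "right")) {
      out[[side]] <- list(
        hindfoot = hindfoot_angle(seq, side),
        foot_rotation = foot_rotation_angle(seq, side),
        coronal_ankle = coronal_ankle_angle(seq, side))
    }
    out$trunk = trunk_coronal_angle(seq)
    out$hip_line_x <- hip_line_angle(seq, axis = "image_x")
  }
  out
}
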