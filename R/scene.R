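# First and last frame indices where all listed keypoints are present.
first_last_valid <- function(seq, ids) {
  ok <- rep(TRUE, n_frames(seq))
  for (id in ids) ok <- ok & !is.na(kp_x(seq, id))
  w <- which(ok)
  if (length(w) < 2) return(NULL)
  c(first = w[1], last = w[length(w)])
}

#' Classify camera view as sagittal or coronal
#'
#' Trunk length (midshoulder KP1 to midhip KP8) fluctuates little over a
#' sagittal walk but changes monotonically with camera distance in a
#' coronal walk. The view is sagittal when the absolute trunk-length
#' difference between the first and last valid frames is below a pixel
#' threshold (99 px at the 1080 px development image height), coronal
#' otherwise. The threshold is rescaled by `image height / ref_height` so
#' the decision is resolution-independent.
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param threshold Pixel threshold at the reference height.
#' @param ref_height Reference image height in pixels for the threshold.
#' @return `"sagittal"` or `"coronal"`.
#' @export
classify_view <- function(seq, threshold = 99, ref_height = 1080) {
  fl <- first_last_valid(seq, c(KP_NECK, KP_MIDHIP))
  if (is.null(fl))
    stop("unclassifiable: trunk keypoints never present in two frames")
  d <- abs(trunk_length(seq, fl["first"]) - trunk_length(seq, fl["last"]))
  scaled <- threshold * seq$resolution[2] / ref_height
  if (d < scaled) "sagittal" else "coronal"
}

#' Walking direction in the coronal view
#'
#' Trunk length grows as the subject approaches the camera, so a negative
#' first-minus-last trunk-length difference means the subject is walking
#' toward the camera and a positive difference means away from it.
#'
#' @param seq A preprocessed `pose_sequence` classified as coronal.
#' @return `"toward_camera"` or `"away_from_camera"`.
#' @export
coronal_direction <- function(seq) {
  fl <- first_last_valid(seq, c(KP_NECK, KP_MIDHIP))
  if (is.null(fl)) stop("trunk keypoints unavailable for direction detection")
  d <- trunk_length(seq, fl["first"]) - trunk_length(seq, fl["last"])
  if (d == 0) stop("ambiguous coronal direction: trunk length unchanged")
  if (d < 0) "toward_camera" else "away_from_camera"
}

#' Walking direction in the sagittal view
#'
#' Tracks the nose (KP0) x position: a negative first-minus-last
#' difference means motion toward larger x, i.e. left to right in the
#' image. When the nose is never visible (e.g. a rear view misrouted to
#' the sagittal branch) the midhip x displacement is used instead and a
#' warning is raised.
#'
#' @param seq A preprocessed `pose_sequence` classified as sagittal.
#' @return `"left_to_right"` or `"right_to_left"`.
#' @export
sagittal_direction <- function(seq) {
  fl <- first_last_valid(seq, KP_NOSE)
  if (is.null(fl)) {
    fl <- first_last_valid(seq, KP_MIDHIP)
    if (is.null(fl)) stop("neither nose nor midhip available for direction")
    warning("nose never detected; falling back to midhip x displacement")
    xs <- kp_x(seq, KP_MIDHIP)
  } else xs <- kp_x(seq, KP_NOSE)
  d <- xs[fl["first"]] - xs[fl["last"]]
  if (abs(d) < 1) stop("ambiguous sagittal direction: < 1 px net displacement")
  if (d < 0) "left_to_right" else "right_to_left"
}

#' Detect view and walking direction
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param config A [evgs_config()] list.
#' @return List with elements `view` (`"sagittal"`/`"coronal"`) and
#'   `direction` (`"left_to_right"`, `"right_to_left"`, `"toward_camera"`
#'   or `"away_from_camera"`).
#' @export
detect_scene <- function(seq, config = evgs_config()) {
  view <- classify_view(seq, threshold = config$view_threshold_px,
                        ref_height = config$view_ref_height)
  direction <- if (view == "sagittal") sagittal_direction(seq)
               else coronal_direction(seq)
  list(view = view, direction = direction)
}
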