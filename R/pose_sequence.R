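# BODY25 keypoint ids (0-based, as emitted by the pose model)
KP_NOSE <- 0L
KP_NECK <- 1L # midshoulder
KP_MIDHIP <- 8L
KP_RHIP <- 9L
KP_RKNEE <- 10L
KP_RANKLE <- 11L
KP_LHIP <- 12L
KP_LKNEE <- 13L
KP_LANKLE <- 14L
KP_LBIGTOE <- 19L
KP_LSMALLTOE <- 20L
KP_LHEEL <- 21L
KP_RBIGTOE <- 22L
KP_RSMALLTOE <- 23L
KP_RHEEL <- 24L

N_KEYPOINTS <- 25L

#' Leg keypoint ids for one side
#'
#' @param side `"left"` or `"right"`.
#' @return Named integer list with elements `hip`, `knee`, `ankle`,
#'   `bigtoe`, `smalltoe`, `heel` (0-based BODY25 ids).
#' @export
kp_side <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") {
    list(hip = KP_LHIP, knee = KP_LKNEE, ankle = KP_LANKLE,
         bigtoe = KP_LBIGTOE, smalltoe = KP_LSMALLTOE, heel = KP_LHEEL)
  } else {
    list(hip = KP_RHIP, knee = KP_RKNEE, ankle = KP_RANKLE,
         bigtoe = KP_RBIGTOE, smalltoe = KP_RSMALLTOE, heel = KP_RHEEL)
  }
}

other_side <- function(side) if (side == "left") "right" else "left"

#' Construct a pose sequence
#'
#' A `pose_sequence` carries per-frame 2-D trajectories of the 25 BODY25
#' keypoints in image coordinates (origin top-left, y increasing downward),
#' together with detection confidences. Missing keypoints are `NA` in both
#' coordinate matrices, never the origin `(0, 0)`.
#'
#' @param x,y Numeric matrices, `n_frames` rows by 25 columns (column `j`
#'   holds keypoint id `j - 1`). `NA` marks a missing keypoint.
#' @param conf Confidence matrix of the same shape, values in `[0, 1]`.
#' @param fs Sampling rate in Hz (default 60).
#' @param resolution Image `c(width, height)` in pixels.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(x, y, conf = NULL, fs = 60,
                          resolution = c(1080, 1920)) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == N_KEYPOINTS, ncol(y) == N_KEYPOINTS,
            nrow(x) == nrow(y), fs > 0, length(resolution) == 2)
  if (is.null(conf)) {
    conf <- matrix(1, nrow(x), N_KEYPOINTS)
    conf[is.na(x)] <- 0
  }
  conf <- as.matrix(conf)
  stopifnot(all(dim(conf) == dim(x)))
  # a missing coordinate must be missing in both axes
  miss <- is.na(x) | is.na(y)
  x[miss] <- NA_real_; y[miss] <- NA_real_
  structure(list(x = x, y = y, conf = conf, fs = fs,
                 resolution = as.numeric(resolution)),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames @ %g Hz, %g x %g px, %.1f%% keypoints present\n",
              n_frames(x), x$fs, x$resolution[1], x$resolution[2],
              100 * mean(!is.na(x$x))))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' Extract one keypoint trajectory
#'
#' @param seq A `pose_sequence`.
#' @param id 0-based BODY25 keypoint id.
#' @return Data frame with columns `x`, `y`, `conf` (one row per frame;
#'   `NA` where missing).
#' @export
kp_trajectory <- function(seq, id) {
  j <- as.integer(id) + 1L
  stopifnot(j >= 1L, j <= N_KEYPOINTS)
  data.frame(x = seq$x[, j], y = seq$y[, j], conf = seq$conf[, j])
}

kp_x <- function(seq, id) seq$x[, as.integer(id) + 1L]
kp_y <- function(seq, id) seq$y[, as.integer(id) + 1L]

#' Trunk length per frame
#'
#' Euclidean distance between the midshoulder (KP1) and midhip (KP8)
#' keypoints; `NA` where either is missing. Trunk length is nearly constant
#' across a sagittal walk but varies with camera distance in a coronal walk,
#' which is the basis of view classification.
#'
#' @param seq A `pose_sequence` (or a single-frame subset).
#' @param frame Optional single frame index (1-based); default all frames.
#' @return Numeric vector of pixel distances (or a single value).
#' @export
trunk_length <- function(seq, frame = NULL) {
  dx <- kp_x(seq, KP_NECK) - kp_x(seq, KP_MIDHIP)
  dy <- kp_y(seq, KP_NECK) - kp_y(seq, KP_MIDHIP)
  d <- sqrt(dx^2 + dy^2)
  if (is.null(frame)) d else d[frame]
}

#' Mirror a pose sequence about the vertical image axis
#'
#' Reflects every x coordinate as `width - x` and swaps anatomical left and
#' right keypoint columns, which is what an actual horizontally mirrored
#' video would produce.
#'
#' @param seq A `pose_sequence`.
#' @return Mirrored `pose_sequence`.
#' @export
mirror_sequence <- function(seq) {
  swap <- seq_len(N_KEYPOINTS) # 1-based columns
  pairs <- list(c(KP_RHIP, KP_LHIP), c(KP_RKNEE, KP_LKNEE),
                c(KP_RANKLE, KP_LANKLE), c(KP_RBIGTOE, KP_LBIGTOE),
                c(KP_RSMALLTOE, KP_LSMALLTOE), c(KP_RHEEL, KP_LHEEL),
                c(2L, 5L), c(3L, 6L), c(4L, 7L),   # arms
                c(15L, 16L), c(17L, 18L))          # eyes, ears
  for (p in pairs) {
    swap[p[1] + 1L] <- p[2] + 1L
    swap[p[2] + 1L] <- p[1] + 1L
  }
  pose_sequence(x = seq$resolution[1] - seq$x[, swap, drop = FALSE],
                y = seq$y[, swap, drop = FALSE],
                conf = seq$conf[, swap, drop = FALSE],
                fs = seq$fs, resolution = seq$resolution)
}

#' Read BODY25 per-frame JSON keypoints
#'
#' Consumes the per-frame JSON dialect of the BODY25 pose model: each frame
#' is one file whose `people` list holds a flat `pose_keypoints_2d` vector
#' of 75 numbers (`x, y, confidence` for each of the 25 keypoints). A
#' keypoint reported as `(0, 0, 0)` is undetected and becomes missing.
#'
#' @param source Directory of per-frame `*.json` files (sorted by filename)
#'   or a single JSON file holding an array of frame objects.
#' @param fs Sampling rate in Hz.
#' @param resolution Image `c(width, height)` in pixels.
#' @return A `pose_sequence`.
#' @section Errors: More than one person in any frame aborts (the scoring
#'   method is single-subject); zero people in more than half of the frames
#'   marks the sequence unusable and aborts.
#' @export
read_body25_json <- function(source, fs = 60, resolution = c(1080, 1920)) {
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0) stop("no JSON frame files in ", source)
    frames <- lapply(files, function(f)
      jsonlite::fromJSON(f, simplifyVector = FALSE))
  } else {
    frames <- jsonlite::fromJSON(source, simplifyVector = FALSE)
    if (!is.null(frames$people)) frames <- list(frames) # single frame object
  }
  n <- length(frames)
  x <- matrix(NA_real_, n, N_KEYPOINTS)
  y <- matrix(NA_real_, n, N_KEYPOINTS)
  cf <- matrix(0, n, N_KEYPOINTS)
  empty <- 0L
  for (i in seq_len(n)) {
    people <- frames[[i]]$people
    if (length(people) > 1)
      stop("multi-person frame ", i,
           ": scoring requires exactly one person in the video")
    if (length(people) == 0) { empty <- empty + 1L; next }
    v <- as.numeric(unlist(people[[1]]$pose_keypoints_2d))
    if (length(v) != 3 * N_KEYPOINTS)
      stop("frame ", i, ": expected 75 values in pose_keypoints_2d, got ",
           length(v))
    m <- matrix(v, ncol = 3, byrow = TRUE)
    undetected <- m[, 3] <= 0 # (0,0,0) convention for undetected keypoints
    m[undetected, 1:2] <- NA_real_
    x[i, ] <- m[, 1]; y[i, ] <- m[, 2]; cf[i, ] <- m[, 3]
  }
  if (empty > n / 2)
    stop("unusable sequence: no person detected in ", empty, " of ", n,
         " frames")
  pose_sequence(x, y, cf, fs = fs, resolution = resolution)
}

#' Write a pose sequence as BODY25 per-frame JSON
#'
#' Inverse of [read_body25_json()]: one `<prefix>_NNNNNN_keypoints.json`
#' file per frame, missing keypoints written as `(0, 0, 0)`.
#'
#' @param seq A `pose_sequence`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_body25_json <- function(seq, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_frames(seq)
  paths <- character(n)
  for (i in seq_len(n)) {
    m <- cbind(seq$x[i, ], seq$y[i, ], seq$conf[i, ])
    miss <- is.na(m[, 1])
    m[miss, ] <- 0
    obj <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = as.vector(t(m)))))
    paths[i] <- file.path(dir, sprintf("%s_%06d_keypoints.json", prefix, i - 1L))
    # 17 significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(obj, paths[i], auto_unbox = TRUE, digits = I(17))
  }
  invisible(paths)
}

#' Read keypoints from a long-format CSV table
#'
#' @param path CSV with columns `frame`, `kp_id`, `x`, `y`, `conf`
#'   (`frame` 0- or 1-based but contiguous; `kp_id` 0-based).
#' @param fs Sampling rate in Hz.
#' @param resolution Image `c(width, height)` in pixels.
#' @return A `pose_sequence`.
#' @export
read_keypoints_csv <- function(path, fs = 60, resolution = c(1080, 1920)) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame", "kp_id", "x", "y", "conf") %in% names(d)))
  fr <- sort(unique(d$frame))
  n <- length(fr)
  x <- matrix(NA_real_, n, N_KEYPOINTS)
  y <- matrix(NA_real_, n, N_KEYPOINTS)
  cf <- matrix(0, n, N_KEYPOINTS)
  i <- match(d$frame, fr)
  j <- as.integer(d$kp_id) + 1L
  idx <- cbind(i, j)
  x[idx] <- d$x; y[idx] <- d$y; cf[idx] <- d$conf
  pose_sequence(x, y, cf, fs = fs, resolution = resolution)
}

#' Write a pose sequence as a long-format CSV table
#'
#' @param seq A `pose_sequence`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_keypoints_csv <- function(seq, path) {
  n <- n_frames(seq)
  d <- data.frame(
    frame = rep(seq_len(n) - 1L, each = N_KEYPOINTS),
    kp_id = rep(0:(N_KEYPOINTS - 1L), n),
    x = as.vector(t(seq$x)),
    y = as.vector(t(seq$y)),
    conf = as.vector(t(seq$conf)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
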