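# Build a pose sequence from a named list of keypoint coordinate matrices
# (n x 2), all other keypoints missing. Names are 0-based keypoint ids.
toy_sequence <- function(points, n = NULL, fs = 60, resolution = c(1920, 1080)) {
  rows <- vapply(points, function(p) if (is.null(dim(p))) 1L else nrow(p),
                 integer(1))
  if (is.null(n)) n <- max(rows)
  x <- matrix(NA_real_, n, 25)
  y <- matrix(NA_real_, n, 25)
  for (id in names(points)) {
    p <- points[[id]]
    if (is.null(dim(p))) p <- matrix(p, 1, 2)
    if (nrow(p) == 1) p <- p[rep(1, n), , drop = FALSE]
    j <- as.integer(id) + 1L
    x[, j] <- p[, 1]; y[, j] <- p[, 2]
  }
  pose_sequence(x, y, fs = fs, resolution = resolution)
}

# single-frame keypoint placement helper for angle tests
one_frame <- function(...) toy_sequence(list(...), n = 1)

quick_walk <- function(seed = 1, n_strides = 3, ...) {
  generate_gait(gait_recipe("sagittal", seed = seed, n_strides = n_strides,
                            ...))
}

# absolute angular difference on the circle (so -180 and 180 coincide)
ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# does each ground-truth event have a detection of matching kind/side
# within `tol` frames?
event_hits <- function(events, truth, tol) {
  hit <- 0L
  for (i in seq_len(nrow(truth))) {
    cand <- events$frame[events$kind == truth$kind[i] &
                           (is.na(events$side) | events$side == truth$side[i])]
    if (length(cand) && min(abs(cand - truth$frame[i])) <= tol) hit <- hit + 1L
  }
  c(hit = hit, total = nrow(truth))
}
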