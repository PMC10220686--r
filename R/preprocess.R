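#' Remove low-confidence keypoints
#'
#' Keypoints whose detection confidence is strictly below `threshold`
#' (default 10%) are set to missing. Frame count and ordering are
#' preserved. Confidences equal to the threshold are kept; set
#' `inclusive = TRUE` to drop them as well.
#'
#' @param seq A `pose_sequence`.
#' @param threshold Confidence threshold in `[0, 1]`.
#' @param inclusive Drop confidences equal to the threshold too.
#' @return A `pose_sequence` with gated keypoints missing.
#' @export
gate_confidence <- function(seq, threshold = 0.10, inclusive = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  drop <- if (inclusive) seq$conf <= threshold else seq$conf < threshold
  seq$x[drop] <- NA_real_
  seq$y[drop] <- NA_real_
  seq
}

# Fill interior NA runs of length <= max_gap in one coordinate vector by a
# cubic spline through the present samples. Leading/trailing runs and longer
# runs are left missing. Requires at least 4 present samples (the caller
# warns and skips otherwise).
fill_gaps_vector <- function(v, max_gap) {
  pres <- which(!is.na(v))
  if (length(pres) == length(v) || length(pres) < 4) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == length(v)) next        # no edge extrapolation
    if (r$lengths[k] > max_gap) next
    v[s:e] <- stats::spline(x = pres, y = v[pres], xout = s:e,
                            method = "fmm")$y
  }
  v
}

#' Fill short keypoint dropouts by cubic-spline interpolation
#'
#' Interior gaps of `max_gap` frames or fewer (default 5, i.e. 0.083 s at
#' 60 Hz) are filled per coordinate by a cubic spline fitted through the
#' present samples of that keypoint. Longer gaps and gaps touching either
#' end of the sequence remain missing; keypoints with fewer than four
#' present samples are left untouched with a warning.
#'
#' @param seq A `pose_sequence`.
#' @param max_gap Maximum gap length, in frames, that is filled.
#' @return A `pose_sequence` with short gaps filled.
#' @export
interpolate_gaps <- function(seq, max_gap = 5) {
  for (j in seq_len(N_KEYPOINTS)) {
    miss <- is.na(seq$x[, j])
    if (!any(miss)) next
    n_present <- sum(!miss)
    if (n_present > 0 && n_present < 4) {
      warning("keypoint ", j - 1L,
              ": fewer than 4 present samples, gaps left unfilled")
      next
    }
    seq$x[, j] <- fill_gaps_vector(seq$x[, j], max_gap)
    seq$y[, j] <- fill_gaps_vector(seq$y[, j], max_gap)
  }
  seq
}

# Zero-phase forward-backward IIR filtering with odd-reflection edge
# padding. signal::filtfilt pads poorly (a constant input comes back
# distorted near the edges), so the padding is done here explicitly.
filtfilt_reflect <- function(b, a, v, padlen) {
  n <- length(v)
  padlen <- min(padlen, n - 1L)
  if (padlen > 0) {
    head_pad <- 2 * v[1] - v[seq(padlen + 1, 2)]
    tail_pad <- 2 * v[n] - v[seq(n - 1, n - padlen)]
    ext <- c(head_pad, v, tail_pad)
  } else ext <- v
  ext <- rev(as.numeric(signal::filter(b, a, ext)))
  ext <- rev(as.numeric(signal::filter(b, a, ext)))
  ext[seq(padlen + 1, padlen + n)]
}

#' Smooth keypoint trajectories with a zero-phase Butterworth filter
#'
#' Applies a dual-pass (forward-backward, hence zero net phase)
#' second-order low-pass Butterworth filter with a 12 Hz cut-off to every
#' keypoint coordinate. Each contiguous present segment is filtered
#' independently; missing spans are preserved. Segments shorter than
#' `3 * (order + 1)` samples are passed through unfiltered with a warning.
#'
#' @param seq A `pose_sequence`.
#' @param cutoff Low-pass cut-off frequency in Hz (must be `< fs / 2`).
#' @param order Filter order of each single pass.
#' @param padlen Odd-reflection padding length in samples for the
#'   forward-backward pass (default 30, long enough for the filter
#'   start-up transient to decay below 1e-9 of the signal; clamped to
#'   the segment length).
#' @return A `pose_sequence` with smoothed trajectories.
#' @export
smooth_trajectories <- function(seq, cutoff = 12, order = 2, padlen = 30L) {
  if (cutoff >= seq$fs / 2)
    stop("invalid cutoff: ", cutoff, " Hz is not below the Nyquist frequency ",
         seq$fs / 2, " Hz")
  bf <- signal::butter(order, cutoff / (seq$fs / 2), type = "low")
  min_len <- 3L * (order + 1L)
  warned <- FALSE
  smooth_one <- function(v) {
    r <- rle(!is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      s <- starts[k]; e <- ends[k]
      if (r$lengths[k] < min_len) {
        if (!warned) {
          warning("segment of ", r$lengths[k],
                  " samples too short to filter; passed through")
          warned <<- TRUE
        }
        next
      }
      v[s:e] <- filtfilt_reflect(bf$b, bf$a, v[s:e], padlen)
    }
    v
  }
  for (j in seq_len(N_KEYPOINTS)) {
    seq$x[, j] <- smooth_one(seq$x[, j])
    seq$y[, j] <- smooth_one(seq$y[, j])
  }
  seq
}

#' Standard preprocessing chain
#'
#' Confidence gating, then cubic-spline gap filling, then zero-phase
#' Butterworth smoothing, with the method's default settings (10% gate,
#' 5-frame gaps, 12 Hz second-order dual-pass).
#'
#' @param seq A `pose_sequence`.
#' @param config A [evgs_config()] list supplying the tunables.
#' @return Preprocessed `pose_sequence`.
#' @export
preprocess <- function(seq, config = evgs_config()) {
  seq <- gate_confidence(seq, threshold = config$conf_threshold,
                         inclusive = config$conf_gate_inclusive)
  seq <- interpolate_gaps(seq, max_gap = config$max_gap)
  smooth_trajectories(seq, cutoff = config$cutoff_hz,
                      order = config$filter_order,
                      padlen = config$filter_padlen)
}
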