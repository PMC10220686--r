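# Local maxima of a signal with minimum separation and minimum prominence.
# NA samples never host a peak and act as barriers when walking out the
# prominence bases. Ties resolve to the earliest frame; endpoints are never
# peaks. Returns sorted frame indices.
find_local_maxima <- function(v, min_sep, min_prom) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(v[i]) || is.na(v[i - 1]) || is.na(v[i + 1])) next
    # strictly greater than the previous, at least as great as the next:
    # plateau peaks resolve to their earliest frame
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(integer(0))
  prominence <- function(i) {
    lo_l <- v[i]; j <- i - 1L
    while (j >= 1 && !is.na(v[j]) && v[j] <= v[i]) {
      lo_l <- min(lo_l, v[j]); j <- j - 1L
    }
    lo_r <- v[i]; j <- i + 1L
    while (j <= n && !is.na(v[j]) && v[j] <= v[i]) {
      lo_r <- min(lo_r, v[j]); j <- j + 1L
    }
    v[i] - max(lo_l, lo_r)
  }
  prom <- vapply(cand, prominence, numeric(1))
  keep <- cand[prom >= min_prom]
  if (length(keep) <= 1) return(keep)
  # enforce minimum separation, keeping the taller peak (earlier on ties)
  ord <- keep[order(-v[keep], keep)]
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(accepted - i) >= min_sep)) accepted <- c(accepted, i)
  }
  sort(accepted)
}

# Peak-finder settings shared by all event detectors: separation of 0.4 s
# (below any plausible stride period) and prominence of 5% of the finite
# signal range.
peak_params <- function(v, fs, config) {
  rng <- range(v, na.rm = TRUE)
  list(min_sep = config$peak_min_sep_s * fs,
       min_prom = config$peak_prom_frac * diff(rng))
}

#' Foot-strike detection signal
#'
#' Coordinate-based (Zeni-style) event signal: the signed forward distance
#' of the heel from the midhip (sacral surrogate, KP8). Foot strikes occur
#' at local maxima. Sagittal view only.
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @param direction `"left_to_right"` or `"right_to_left"`.
#' @return Per-frame numeric vector (`NA` where keypoints missing).
#' @export
strike_signal <- function(seq, side, direction) {
  s <- if (direction == "left_to_right") 1 else if (direction == "right_to_left") -1
       else stop("strike_signal requires a sagittal direction")
  k <- kp_side(side)
  s * (kp_x(seq, k$heel) - kp_x(seq, KP_MIDHIP))
}

#' Foot-off detection signal
#'
#' Signed posterior distance of the big toe from the midhip; foot offs
#' occur at local maxima (toe furthest behind the pelvis). Sagittal only.
#'
#' @inheritParams strike_signal
#' @return Per-frame numeric vector.
#' @export
off_signal <- function(seq, side, direction) {
  s <- if (direction == "left_to_right") 1 else if (direction == "right_to_left") -1
       else stop("off_signal requires a sagittal direction")
  k <- kp_side(side)
  s * (kp_x(seq, KP_MIDHIP) - kp_x(seq, k$bigtoe))
}

#' Inter-toe distance
#'
#' Euclidean distance between the two big-toe keypoints (KP19, KP22). Its
#' minima mark the feet passing each other: mid-midstance of the stance
#' leg and simultaneously mid-midswing of the swing leg.
#'
#' @param seq A `pose_sequence`.
#' @param frame Optional single frame index.
#' @return Numeric vector of pixel distances (or one value).
#' @export
inter_toe_distance <- function(seq, frame = NULL) {
  dx <- kp_x(seq, KP_LBIGTOE) - kp_x(seq, KP_RBIGTOE)
  dy <- kp_y(seq, KP_LBIGTOE) - kp_y(seq, KP_RBIGTOE)
  d <- sqrt(dx^2 + dy^2)
  if (is.null(frame)) d else d[frame]
}

# Assign each mid-midstance frame the side whose strike most recently
# preceded it (the current stance foot); NA when no strike precedes.
assign_stance_side <- function(frames, strikes) {
  vapply(frames, function(f) {
    prior <- strikes[strikes$frame <= f, , drop = FALSE]
    if (nrow(prior) == 0) NA_character_ else prior$side[which.max(prior$frame)]
  }, character(1))
}

#' Detect mid-midstance frames
#'
#' Local minima of the inter-toe distance, with the same separation and
#' prominence rules as the other event detectors. When a strike table is
#' supplied each minimum is attributed to the current stance side.
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param strikes Optional data frame of strikes (`frame`, `side`).
#' @param config A [evgs_config()] list.
#' @return Data frame with columns `frame`, `side`, `kind`.
#' @export
detect_mid_midstance <- function(seq, strikes = NULL, config = evgs_config()) {
  d <- inter_toe_distance(seq)
  pp <- peak_params(-d, seq$fs, config)
  fr <- find_local_maxima(-d, pp$min_sep, pp$min_prom)
  side <- if (is.null(strikes) || nrow(strikes) == 0) rep(NA_character_, length(fr))
          else assign_stance_side(fr, strikes)
  data.frame(frame = fr, side = side, kind = rep("mid_midstance", length(fr)),
             stringsAsFactors = FALSE)
}

# Sagittal detection of strikes and offs for one side.
detect_side_events <- function(seq, side, direction, config) {
  out <- list()
  for (kind in c("foot_strike", "foot_off")) {
    sig <- if (kind == "foot_strike") strike_signal(seq, side, direction)
           else off_signal(seq, side, direction)
    if (all(is.na(sig)) || diff(range(sig, na.rm = TRUE)) == 0) {
      fr <- integer(0)
    } else {
      pp <- peak_params(sig, seq$fs, config)
      fr <- find_local_maxima(sig, pp$min_sep, pp$min_prom)
    }
    out[[kind]] <- data.frame(frame = fr, side = rep(side, length(fr)),
                              kind = rep(kind, length(fr)),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Coronal strikes: maxima of the inter-toe distance (the feet are furthest
# apart in the image at touchdown). The striking side is the leading foot,
# which is the foot closer to the camera when walking toward it (larger
# ankle image y) and the farther foot when walking away (smaller y).
detect_coronal_strikes <- function(seq, direction, config) {
  d <- inter_toe_distance(seq)
  if (all(is.na(d)) || diff(range(d, na.rm = TRUE)) == 0)
    return(data.frame(frame = integer(0), side = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  pp <- peak_params(d, seq$fs, config)
  fr <- find_local_maxima(d, pp$min_sep, pp$min_prom)
  ly <- kp_y(seq, KP_LANKLE); ry <- kp_y(seq, KP_RANKLE)
  side <- vapply(fr, function(f) {
    if (is.na(ly[f]) || is.na(ry[f])) return(NA_character_)
    lower_is_left <- ly[f] > ry[f]
    if (direction == "toward_camera") {
      if (lower_is_left) "left" else "right"
    } else {
      if (lower_is_left) "right" else "left"
    }
  }, character(1))
  data.frame(frame = fr, side = side, kind = rep("foot_strike", length(fr)),
             stringsAsFactors = FALSE)
}

#' Detect all gait events
#'
#' Sagittal view: foot strikes and foot offs per side from the
#' pelvis-relative heel/toe displacement signals, plus mid-midstance
#' frames from the inter-toe distance. Coronal view: stride boundaries
#' (strikes) from inter-toe-distance maxima and mid-midstance from its
#' minima; per-side displacement signals are not defined in this view.
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param view `"sagittal"` or `"coronal"`.
#' @param direction Walking direction label.
#' @param config A [evgs_config()] list.
#' @return Data frame of events (`frame`, `side`, `kind`), ordered by frame.
#' @export
detect_events <- function(seq, view, direction, config = evgs_config()) {
  if (view == "sagittal") {
    ev <- rbind(detect_side_events(seq, "left", direction, config),
                detect_side_events(seq, "right", direction, config))
  } else {
    ev <- detect_coronal_strikes(seq, direction, config)
  }
  strikes <- ev[ev$kind == "foot_strike", , drop = FALSE]
  mm <- detect_mid_midstance(seq, strikes, config)
  ev <- rbind(ev, mm)
  ev <- ev[order(ev$frame, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Segment events into strides
#'
#' A stride runs between two consecutive foot strikes of the same foot.
#' Every side with at least two strikes contributes strides; all events
#' whose frame falls inside `[start, end]` are attached to the stride.
#'
#' @param events Event data frame from [detect_events()].
#' @param view `"sagittal"` or `"coronal"` (recorded on each stride).
#' @return List of strides, each a list with `side`, `start`, `end` and
#'   `events` (the contained event rows). Ordered by start frame; the
#'   first stride belongs to the side of the earliest strike.
#' @export
segment_strides <- function(events, view = "sagittal") {
  strikes <- events[events$kind == "foot_strike" & !is.na(events$side), ,
                    drop = FALSE]
  strides <- list()
  for (side in c("left", "right")) {
    sf <- sort(strikes$frame[strikes$side == side])
    if (length(sf) < 2) next
    for (k in seq_len(length(sf) - 1)) {
      within <- events[events$frame >= sf[k] & events$frame <= sf[k + 1], ,
                       drop = FALSE]
      strides[[length(strides) + 1]] <-
        list(side = side, start = sf[k], end = sf[k + 1],
             view = view, events = within)
    }
  }
  if (length(strides) == 0)
    stop("no strides: fewer than two foot strikes on both sides")
  strides[order(vapply(strides, `[[`, numeric(1), "start"))]
}

#' Count strides per side
#' @param strides Result of [segment_strides()].
#' @return Named integer vector `c(left = , right = )`.
#' @export
stride_counts <- function(strides) {
  sides <- vapply(strides, `[[`, character(1), "side")
  c(left = sum(sides == "left"), right = sum(sides == "right"))
}
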