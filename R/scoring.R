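#' EVGS parameter names
#'
#' @return Character vector of length 17, indexed by parameter number.
#' @export
evgs_parameter_names <- function() {
  c("Initial contact",                        # 1
    "Heel lift",                              # 2
    "Max ankle dorsiflexion in stance",       # 3
    "Hindfoot valgus/varus",                  # 4
    "Foot rotation",                          # 5
    "Foot clearance in swing",                # 6
    "Max ankle dorsiflexion in swing",        # 7
    "Knee progression angle",                 # 8
    "Peak knee extension in stance",          # 9
    "Knee extension in terminal swing",       # 10
    "Peak knee flexion in swing",             # 11
    "Peak hip extension in stance",           # 12
    "Peak hip flexion in swing",              # 13
    "Max pelvic obliquity in stance",         # 14
    "Pelvic rotation in midstance",           # 15
    "Peak sagittal trunk position",           # 16
    "Max lateral trunk shift")                # 17
}

SAGITTAL_PARAMS <- c(1L, 2L, 3L, 6L, 7L, 9L, 10L, 11L, 12L, 13L, 15L, 16L)
CORONAL_PARAMS <- c(4L, 5L, 8L, 14L, 17L)

#' Score initial contact (#1)
#'
#' Classifies the foot posture at the foot-strike frame from the angle of
#' the heel-to-midtoe line against the image x-axis: heel contact above
#' 20 degrees (toes up), flat foot between 0 and 20 degrees inclusive,
#' toe contact below 0.
#'
#' @param angle Foot-axis angle at the strike frame, degrees.
#' @param flat_max Upper bound of the flat-foot window (default 20).
#' @return List with `ordinal`, `label`, `value`.
#' @export
score_initial_contact <- function(angle, flat_max = 20) {
  if (is.na(angle)) return(unscorable("foot axis missing at strike"))
  if (angle > flat_max) entry(0L, "heel contact", angle)
  else if (angle >= 0) entry(1L, "flat foot contact", angle)
  else entry(2L, "toe contact", angle)
}

#' Score peak sagittal trunk position (#16)
#'
#' Normal within 5 degrees of vertical either way; moderate for more than
#' 5 degrees backward or a forward lean up to 15 degrees; marked beyond
#' 15 degrees forward.
#'
#' @param angle Peak trunk angle over the stride, degrees, forward
#'   positive.
#' @return List with `ordinal`, `label`, `value`.
#' @export
score_trunk_sagittal <- function(angle) {
  if (is.na(angle)) return(unscorable("trunk keypoints missing"))
  if (angle > 15) entry(2L, "marked forward lean", angle)
  else if (angle > 5) entry(1L, "moderate forward lean", angle)
  else if (angle < -5) entry(1L, "backward lean", angle)
  else entry(0L, "normal", angle)
}

#' Score maximum lateral trunk shift (#17)
#'
#' Coronal trunk angle signed toward the stance side: 0-5 degrees normal,
#' negative (away from the stance leg) reduced, 6-15 moderate, beyond 15
#' marked.
#'
#' @param angle Trunk angle toward the stance side, degrees.
#' @return List with `ordinal`, `label`, `value`.
#' @export
score_lateral_trunk_shift <- function(angle) {
  if (is.na(angle)) return(unscorable("trunk keypoints missing"))
  if (angle < 0) entry(1L, "reduced", angle)
  else if (angle > 15) entry(2L, "marked", angle)
  else if (angle > 5) entry(1L, "moderate", angle)
  else entry(0L, "normal", angle)
}

#' Score knee progression angle (#8)
#'
#' Surrogate rule on the coronal ankle angle: within +/-25 degrees
#' normal, beyond +25 internal rotation, below -25 external rotation.
#'
#' @param angle Coronal ankle angle, degrees.
#' @param threshold Band half-width (default 25).
#' @return List with `ordinal`, `label`, `value`.
#' @export
score_knee_progression <- function(angle, threshold = 25) {
  if (is.na(angle)) return(unscorable("ankle/foot keypoints missing"))
  if (angle > threshold) entry(1L, "internal rotation", angle)
  else if (angle < -threshold) entry(1L, "external rotation", angle)
  else entry(0L, "normal", angle)
}

#' Score heel lift (#2)
#'
#' With a flat midstance posture, heel lift is normal when the stance heel
#' leaves the ground between the feet-level instant (mid-midstance) and
#' the opposite foot strike, early before it, delayed after it. A
#' toe-only stance scores "no heel contact", a heel-only stance "no
#' forefoot contact".
#'
#' @param lift_frame First sustained heel-rise frame (`NA` when the heel
#'   never lifts during stance).
#' @param level_frame Mid-midstance frame of this stance.
#' @param opp_strike_frame Opposite foot-strike frame.
#' @param stance_class `"flat"`, `"toe_only"` or `"heel_only"` midstance
#'   posture.
#' @return List with `ordinal`, `label`, `value` (the lift frame).
#' @export
score_heel_lift <- function(lift_frame, level_frame, opp_strike_frame,
                            stance_class = "flat") {
  if (stance_class == "toe_only")
    return(entry(2L, "no heel contact", NA_real_))
  if (stance_class == "heel_only")
    return(entry(2L, "no forefoot contact", NA_real_))
  if (is.na(level_frame) || is.na(opp_strike_frame))
    return(unscorable("reference events missing for heel lift"))
  if (is.na(lift_frame)) return(entry(1L, "delayed", NA_real_))
  if (lift_frame <= level_frame) entry(1L, "early", lift_frame)
  else if (lift_frame <= opp_strike_frame) entry(0L, "normal", lift_frame)
  else entry(1L, "delayed", lift_frame)
}

#' Score foot clearance in swing (#6)
#'
#' Evaluated at the instant the swing foot passes the stance foot
#' (mid-midstance of the stance leg). Image y is smaller higher up, and
#' "above" requires clearing by more than `tol` pixels.
#'
#' @param swing_toe_y,swing_heel_y Swing-foot big-toe and heel y.
#' @param stance_toe_y,stance_heel_y Stance-foot big-toe and heel y.
#' @param shank_mid_y Midpoint y of the stance ankle-knee segment (high
#'   step reference).
#' @param tol Clearance margin in pixels.
#' @param high_step_ordinal Ordinal assigned to a high step.
#' @return List with `ordinal`, `label`, `value` (toe clearance px).
#' @export
score_foot_clearance <- function(swing_toe_y, swing_heel_y, stance_toe_y,
                                 stance_heel_y, shank_mid_y, tol = 3,
                                 high_step_ordinal = 1L) {
  vals <- c(swing_toe_y, swing_heel_y, stance_toe_y, stance_heel_y)
  if (any(is.na(vals)))
    return(unscorable("foot keypoints missing at passing frame"))
  toe_clear <- stance_toe_y - swing_toe_y
  if (!is.na(shank_mid_y) && swing_toe_y < shank_mid_y)
    return(entry(as.integer(high_step_ordinal), "high step", toe_clear))
  toe_above <- toe_clear > tol
  heel_above <- (stance_heel_y - swing_heel_y) > tol
  if (toe_above && heel_above) entry(0L, "full clearance", toe_clear)
  else if (heel_above) entry(1L, "reduced clearance", toe_clear)
  else entry(2L, "no clearance", toe_clear)
}

entry <- function(ordinal, label, value) {
  list(ordinal = as.integer(ordinal), label = label, value = value,
       scorable = TRUE, reason = NA_character_)
}

unscorable <- function(reason) {
  list(ordinal = NA_integer_, label = NA_character_, value = NA_real_,
       scorable = FALSE, reason = reason)
}

band_entry <- function(value, table) {
  if (is.na(value)) return(unscorable("measurement unavailable"))
  b <- score_band(value, table)
  entry(b$ordinal, b$label, value)
}

# window extremum helpers -------------------------------------------------

win_extremum <- function(v, lo, hi, which = c("max", "min")) {
  which <- match.arg(which)
  if (is.na(lo) || is.na(hi) || hi < lo) return(NA_real_)
  w <- v[lo:hi]
  if (all(is.na(w))) return(NA_real_)
  if (which == "max") max(w, na.rm = TRUE) else min(w, na.rm = TRUE)
}

stride_event_frame <- function(stride, kind, side = NULL, strict = FALSE) {
  ev <- stride$events
  sel <- ev$kind == kind
  if (!is.null(side)) sel <- sel & !is.na(ev$side) & ev$side == side
  if (strict) sel <- sel & ev$frame > stride$start & ev$frame < stride$end
  fr <- ev$frame[sel]
  if (length(fr) == 0) NA_integer_ else fr[1]
}

# First sustained heel rise during stance: heel y at least `rise` px above
# (i.e. numerically below) the early-stance plateau median for `sustain`
# consecutive frames. Returns NA when the heel never lifts.
detect_heel_lift_frame <- function(heel_y, start, off, rise = 3, sustain = 3) {
  if (is.na(off) || off <= start) return(NA_integer_)
  q <- start + max(2L, round(0.25 * (off - start)))
  plateau <- stats::median(heel_y[start:q], na.rm = TRUE)
  if (is.na(plateau)) return(NA_integer_)
  lifted <- !is.na(heel_y[start:off]) & (plateau - heel_y[start:off]) >= rise
  r <- rle(lifted)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= sustain)
      return(start + (ends[k] - r$lengths[k] + 1L) - 1L)
  }
  NA_integer_
}

# per-stride scoring ------------------------------------------------------

score_stride_sagittal <- function(seq, stride, ang, direction, config) {
  side <- stride$side
  a <- ang[[side]]
  off <- stride_event_frame(stride, "foot_off", side)
  mms_own <- stride_event_frame(stride, "mid_midstance", side)
  opp_strike <- stride_event_frame(stride, "foot_strike", other_side(side),
                                   strict = TRUE)
  start <- stride$start; end <- stride$end
  swing_lo <- if (!is.na(off)) off else NA_integer_
  res <- list()

  res[["1"]] <- score_initial_contact(a$foot_axis[start],
                                      flat_max = config$flat_foot_max_deg)

  # trunk: signed angle at the frame of largest deviation over the stride
  tr <- ang$trunk[start:end]
  res[["16"]] <- if (all(is.na(tr))) unscorable("trunk keypoints missing")
                 else score_trunk_sagittal(tr[which.max(abs(tr))])

  if (is.na(off)) {
    stance_na <- unscorable("foot-off event not detected in stride")
    res[["3"]] <- res[["9"]] <- res[["12"]] <- stance_na
    res[["7"]] <- res[["10"]] <- res[["11"]] <- res[["13"]] <- stance_na
  } else {
    res[["3"]] <- band_entry(win_extremum(a$dorsiflexion, start, off, "max"),
                             config$bands$p3)
    res[["9"]] <- band_entry(win_extremum(a$knee, start, off, "min"),
                             config$bands$p9)
    res[["12"]] <- band_entry(win_extremum(a$hip, start, off, "min"),
                              config$bands$p12)
    res[["7"]] <- band_entry(win_extremum(a$dorsiflexion, off, end, "max"),
                             config$bands$p7)
    res[["11"]] <- band_entry(win_extremum(a$knee, off, end, "max"),
                              config$bands$p11)
    res[["13"]] <- band_entry(win_extremum(a$hip, off, end, "max"),
                              config$bands$p13)
    ts_lo <- end - max(1L, round(config$terminal_swing_frac * (end - off)))
    res[["10"]] <- band_entry(win_extremum(a$knee, ts_lo, end, "min"),
                              config$bands$p10)
  }

  # heel lift
  k <- kp_side(side)
  heel_y <- kp_y(seq, k$heel)
  # midstance posture; checked both at mid-midstance and in early stance
  # so that an early heel lift (flat foot early, heel up by midstance) is
  # not mistaken for toe walking (toes-only throughout)
  stance_class <- "flat"
  if (!is.na(mms_own)) {
    pitch <- a$foot_axis[mms_own]
    early_f <- if (!is.na(off)) start + round(0.25 * (off - start)) else mms_own
    pitch_e <- a$foot_axis[early_f]
    if (is.na(pitch_e)) pitch_e <- pitch
    if (!is.na(pitch)) {
      thr <- config$midstance_pitch_deg
      if (pitch < -thr && pitch_e < -thr) stance_class <- "toe_only"
      else if (pitch > thr && pitch_e > thr) stance_class <- "heel_only"
    }
  }
  lift <- if (stance_class == "flat")
    detect_heel_lift_frame(heel_y, start, off,
                           rise = config$heel_lift_rise_px,
                           sustain = config$heel_lift_sustain)
  else NA_integer_
  res[["2"]] <- score_heel_lift(lift, mms_own, opp_strike, stance_class)

  # foot clearance: this leg swings while the opposite leg is in stance
  pf <- stride_event_frame(stride, "mid_midstance", other_side(side))
  if (is.na(pf)) {
    res[["6"]] <- unscorable("opposite-stance mid-midstance not detected")
  } else {
    ko <- kp_side(other_side(side))
    shank_mid <- (kp_y(seq, ko$ankle)[pf] + kp_y(seq, ko$knee)[pf]) / 2
    res[["6"]] <- score_foot_clearance(
      swing_toe_y = kp_y(seq, k$bigtoe)[pf],
      swing_heel_y = heel_y[pf],
      stance_toe_y = kp_y(seq, ko$bigtoe)[pf],
      stance_heel_y = kp_y(seq, ko$heel)[pf],
      shank_mid_y = shank_mid,
      tol = config$clearance_tol_px,
      high_step_ordinal = config$high_step_ordinal)
  }

  # pelvic rotation surrogate (low confidence in this projection)
  res[["15"]] <- if (is.na(mms_own)) unscorable("mid-midstance not detected")
                 else band_entry(abs(ang$hip_line_y[mms_own]), config$bands$p15)

  res
}

score_stride_coronal <- function(seq, stride, ang, direction, config) {
  side <- stride$side
  a <- ang[[side]]
  mms_own <- stride_event_frame(stride, "mid_midstance", side)
  start <- stride$start; end <- stride$end
  res <- list()

  res[["14"]] <- band_entry(win_extremum(abs(ang$hip_line_x), start, end, "max"),
                            config$bands$p14)

  if (is.na(mms_own)) {
    no_mms <- unscorable("own-stance mid-midstance not detected")
    res[["17"]] <- res[["8"]] <- res[["5"]] <- res[["4"]] <- no_mms
    return(res)
  }

  # trunk angle signed toward the stance side
  k <- kp_side(side)
  st_x <- kp_x(seq, k$ankle)[mms_own]
  mh_x <- kp_x(seq, KP_MIDHIP)[mms_own]
  base <- ang$trunk[mms_own]
  res[["17"]] <- if (is.na(base) || is.na(st_x) || is.na(mh_x))
    unscorable("trunk or stance keypoints missing at midstance")
  else score_lateral_trunk_shift(base * sign(st_x - mh_x))

  res[["8"]] <- score_knee_progression(a$coronal_ankle[mms_own],
                                       threshold = config$knee_progression_deg)
  res[["5"]] <- band_entry(a$foot_rotation[mms_own], config$bands$p5)

  # hindfoot: valgus positive when the heel-to-ankle line leans toward
  # the body midline
  hf <- a$hindfoot[mms_own]
  heel_x <- kp_x(seq, k$heel)[mms_own]
  res[["4"]] <- if (is.na(hf) || is.na(heel_x) || is.na(mh_x))
    unscorable("hindfoot keypoints missing at midstance")
  else {
    toward_midline <- sign(mh_x - heel_x)
    v <- abs(hf) * ifelse(sign(hf) == toward_midline | hf == 0, 1, -1)
    band_entry(v, config$bands$p4)
  }

  res
}

# most frequent ordinal; ties resolve to the worse (higher) score
mode_worse <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_integer_)
  tab <- table(v)
  cands <- as.integer(names(tab)[tab == max(tab)])
  max(cands)
}

#' Compile the per-leg EVGS report
#'
#' Scores every applicable parameter for every stride, then aggregates to
#' a final per-leg ordinal as the most frequent per-stride score (ties go
#' to the worse score). Parameters of the other view are flagged not
#' applicable; parameters that could not be measured carry a reason and
#' are never silently scored 0.
#'
#' @param seq A preprocessed `pose_sequence`.
#' @param scene Result of [detect_scene()].
#' @param events Result of [detect_events()].
#' @param strides Result of [segment_strides()].
#' @param config A [evgs_config()] list.
#' @return An `evgs_report`: list with `scores` (final per parameter and
#'   side), `per_stride` (every stride-level entry) and `meta`.
#' @export
compile_report <- function(seq, scene, events, strides, config = evgs_config()) {
  ang <- angle_series(seq, scene$view, scene$direction)
  applicable <- if (scene$view == "sagittal") SAGITTAL_PARAMS else CORONAL_PARAMS
  scorer <- if (scene$view == "sagittal") score_stride_sagittal
            else score_stride_coronal
  nm <- evgs_parameter_names()

  per <- list()
  for (i in seq_along(strides)) {
    st <- strides[[i]]
    res <- scorer(seq, st, ang, scene$direction, config)
    for (p in names(res)) {
      e <- res[[p]]
      per[[length(per) + 1]] <- data.frame(
        parameter = as.integer(p), side = st$side, stride = i,
        value = e$value, ordinal = e$ordinal, label = e$label,
        scorable = e$scorable, reason = e$reason, stringsAsFactors = FALSE)
    }
  }
  per_stride <- do.call(rbind, per)

  rows <- list()
  for (side in c("left", "right")) {
    for (p in 1:17) {
      if (!(p %in% applicable)) {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = p, name = nm[p], side = side, ordinal = NA_integer_,
          label = "not applicable in this view", value = NA_real_,
          n_strides = 0L, scorable = FALSE,
          reason = "parameter belongs to the other camera view",
          stringsAsFactors = FALSE)
        next
      }
      sub <- per_stride[per_stride$parameter == p & per_stride$side == side, ,
                        drop = FALSE]
      ord <- mode_worse(sub$ordinal)
      if (nrow(sub) == 0 || is.na(ord)) {
        reason <- if (nrow(sub) == 0) "no stride on this side"
                  else paste(unique(stats::na.omit(sub$reason)), collapse = "; ")
        rows[[length(rows) + 1]] <- data.frame(
          parameter = p, name = nm[p], side = side, ordinal = NA_integer_,
          label = "unscorable", value = NA_real_,
          n_strides = nrow(sub), scorable = FALSE, reason = reason,
          stringsAsFactors = FALSE)
      } else {
        match_rows <- sub[!is.na(sub$ordinal) & sub$ordinal == ord, ,
                          drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          parameter = p, name = nm[p], side = side, ordinal = ord,
          label = match_rows$label[1],
          value = stats::median(match_rows$value, na.rm = TRUE),
          n_strides = nrow(sub), scorable = TRUE, reason = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, rows)
  structure(list(scores = scores, per_stride = per_stride,
                 meta = list(view = scene$view, direction = scene$direction,
                             stride_counts = stride_counts(strides),
                             n_frames = n_frames(seq), fs = seq$fs)),
            class = "evgs_report")
}

#' @export
print.evgs_report <- function(x, ...) {
  cat(sprintf("<evgs_report> %s view, %s; strides L=%d R=%d\n",
              x$meta$view, x$meta$direction,
              x$meta$stride_counts["left"], x$meta$stride_counts["right"]))
  sc <- x$scores[x$scores$scorable | !grepl("other camera view", x$scores$reason), ]
  for (side in c("left", "right")) {
    cat(sprintf("  %s leg:\n", side))
    sub <- sc[sc$side == side, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      if (r$scorable)
        cat(sprintf("    #%-2d %-34s %d (%s)%s\n", r$parameter, r$name,
                    r$ordinal, r$label,
                    if (!is.na(r$value)) sprintf(" [%.1f]", r$value) else ""))
      else
        cat(sprintf("    #%-2d %-34s unscorable: %s\n", r$parameter, r$name,
                    r$reason))
    }
  }
  invisible(x)
}
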