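#' Synthetic gait recipe
#'
#' Parameters of the planar linked-segment walker used to generate BODY25
#' keypoint walks with known ground truth. Segment lengths are pixels at
#' `scale = 1` for a roughly 1700 px tall adult; the default scale 0.6
#' fits a multi-stride walk into a 1920 x 1080 landscape frame at the
#' default 480 px stride. Cadence 100 steps/min at 60 Hz gives a 72-frame
#' stride. Deviation switches inject the gait patterns the scorer is
#' meant to sense (trunk lean, contact type, clearance mode, heel-lift
#' timing, crouch, pelvic obliquity, lateral trunk shift, foot rotation).
#'
#' @param view `"sagittal"` or `"coronal"`.
#' @param direction Walking direction; defaults to `"left_to_right"`
#'   (sagittal) or `"toward_camera"` (coronal).
#' @param fs Sampling rate, Hz.
#' @param cadence Steps per minute.
#' @param n_strides Strides per leg to generate.
#' @param scale Global body scale factor.
#' @param stride_px Stride length in pixels at scale 1.
#' @param noise_sd Gaussian pixel noise added to every coordinate.
#' @param dropout Probability that a keypoint-frame is reported with a
#'   confidence below the 10% gate.
#' @param seed Integer seed fixing the full output.
#' @param trunk_lean_deg Sagittal trunk lean, forward positive.
#' @param contact Initial contact type: `"heel"`, `"flat"` or `"toe"`.
#' @param clearance Swing clearance mode: `"full"`, `"reduced"`,
#'   `"none"` or `"high"`.
#' @param heel_lift Heel-lift timing: `"normal"`, `"early"`, `"delayed"`,
#'   `"no_heel"` (toe walking) or `"no_forefoot"` (heel walking).
#' @param crouch_deg Extra knee flexion added throughout stance.
#' @param pelvic_rotation_deg Transverse pelvis rotation (sagittal
#'   hip-keypoint separation surrogate).
#' @param pelvic_obliquity_deg Coronal pelvis obliquity (one hip raised).
#' @param trunk_shift_deg Coronal lateral trunk lean toward the stance
#'   side.
#' @param foot_rotation_deg Coronal external foot rotation.
#' @return A `gait_recipe` list.
#' @export
gait_recipe <- function(view = c("sagittal", "coronal"), direction = NULL,
                        fs = 60, cadence = 100, n_strides = 5, scale = 0.6,
                        stride_px = 480, noise_sd = 0, dropout = 0, seed = 1,
                        trunk_lean_deg = 0,
                        contact = c("heel", "flat", "toe"),
                        clearance = c("full", "reduced", "none", "high"),
                        heel_lift = c("normal", "early", "delayed",
                                      "no_heel", "no_forefoot"),
                        crouch_deg = 0, pelvic_rotation_deg = 3,
                        pelvic_obliquity_deg = 0, trunk_shift_deg = 0,
                        foot_rotation_deg = 0) {
  view <- match.arg(view)
  if (is.null(direction))
    direction <- if (view == "sagittal") "left_to_right" else "toward_camera"
  sag_dirs <- c("left_to_right", "right_to_left")
  cor_dirs <- c("toward_camera", "away_from_camera")
  if (view == "sagittal" && !(direction %in% sag_dirs))
    stop("invalid recipe: sagittal view with direction ", direction)
  if (view == "coronal" && !(direction %in% cor_dirs))
    stop("invalid recipe: coronal view with direction ", direction)
  stopifnot(fs > 0, cadence > 0, n_strides >= 1, scale > 0, stride_px > 0,
            noise_sd >= 0, dropout >= 0, dropout < 1)
  rec <- list(view = view, direction = direction, fs = fs, cadence = cadence,
              n_strides = n_strides, scale = scale, stride_px = stride_px,
              noise_sd = noise_sd, dropout = dropout, seed = as.integer(seed),
              trunk_lean_deg = trunk_lean_deg, contact = match.arg(contact),
              clearance = match.arg(clearance),
              heel_lift = match.arg(heel_lift), crouch_deg = crouch_deg,
              pelvic_rotation_deg = pelvic_rotation_deg,
              pelvic_obliquity_deg = pelvic_obliquity_deg,
              trunk_shift_deg = trunk_shift_deg,
              foot_rotation_deg = foot_rotation_deg)
  class(rec) <- c("gait_recipe", "list")
  rec
}

# rotate a foot-frame offset (px forward along the sole, py image-down) by
# pitch theta (degrees, toes-up positive); `s` mirrors forward for
# right-to-left internal generation (always +1 here: mirroring is applied
# to the finished sequence instead)
rot_off <- function(px, py, theta) {
  th <- theta * pi / 180
  c(px * cos(th) + py * sin(th), py * cos(th) - px * sin(th))
}

# hip->ankle two-link inverse kinematics with anterior knee bend
ik_knee <- function(hx, hy, ax, ay, L1, L2) {
  dx <- ax - hx; dy <- ay - hy
  d <- sqrt(dx^2 + dy^2)
  d <- min(max(d, abs(L1 - L2) + 0.5), L1 + L2 - 0.5)
  a1 <- acos(pmin(1, pmax(-1, (L1^2 + d^2 - L2^2) / (2 * L1 * d))))
  a2 <- acos(pmin(1, pmax(-1, (L2^2 + d^2 - L1^2) / (2 * L2 * d))))
  phi <- atan2(dx, dy)          # hip-ankle line angle from image-down
  thigh <- phi + a1             # anterior bend
  list(knee = c(hx + L1 * sin(thigh), hy + L1 * cos(thigh)),
       thigh_deg = thigh * 180 / pi,
       knee_deg = (a1 + a2) * 180 / pi)
}

leg_d_for_knee <- function(theta_deg, L1, L2) {
  sqrt(L1^2 + L2^2 + 2 * L1 * L2 * cos(theta_deg * pi / 180))
}

# cosine interpolation through knots (w in [0,1])
cos_interp <- function(w, knots_w, knots_v) {
  i <- findInterval(w, knots_w, all.inside = TRUE)
  u <- (w - knots_w[i]) / (knots_w[i + 1] - knots_w[i])
  knots_v[i] + (knots_v[i + 1] - knots_v[i]) * 0.5 * (1 - cos(pi * u))
}

synth_sagittal <- function(rec) {
  sc <- rec$scale
  P <- round(2 * rec$fs * 60 / rec$cadence)
  duty <- 0.6; settle <- 0.1
  S <- rec$stride_px * sc
  Lf <- 90 * sc; ank_f <- 18 * sc; ank_u <- 28 * sc
  L1 <- 165 * sc; L2 <- 155 * sc
  trunk <- 300 * sc
  lead <- 120 * sc
  ground <- 940

  theta_c <- switch(rec$contact, heel = 25, flat = 8, toe = -10)
  theta_po <- -40
  hl_ph <- switch(rec$heel_lift, normal = 0.36, early = 0.18, delayed = 0.55,
                  no_heel = NA, no_forefoot = NA)
  clear_px <- switch(rec$clearance, full = 28 * sc, reduced = 45 * sc,
                     none = 2 * sc, high = 130 * sc)
  theta_mid <- switch(rec$clearance, full = -15, reduced = NA, none = 0,
                      high = 5)

  # hip heights from stance knee-flexion targets
  k_ms <- 8 + rec$crouch_deg; k_st <- 10 + rec$crouch_deg
  d_ms <- leg_d_for_knee(k_ms, L1, L2)
  d_st <- leg_d_for_knee(k_st, L1, L2)
  h_hi <- sqrt(max(d_ms^2 - (20 * sc)^2, (0.5 * d_ms)^2)) + ank_u
  h_lo <- sqrt(max(d_st^2 - lead^2, (0.5 * d_st)^2)) + 33 * sc

  t_R0 <- 31
  N <- t_R0 + rec$n_strides * P + 30
  v <- S / P
  hx0 <- 60
  adx <- rot_off(ank_f, -ank_u, theta_c)[1]

  strike_list <- list(
    right = t_R0 + (-1:(rec$n_strides + 1)) * P,
    left = t_R0 + round(P / 2) + (-1:(rec$n_strides + 1)) * P)
  land_list <- lapply(strike_list, function(st) hx0 + v * st - adx + lead)

  hip_x <- hx0 + v * seq_len(N)
  u <- ((seq_len(N) - t_R0) %% (P / 2)) / (P / 2)
  hip_y <- ground - (h_lo + (h_hi - h_lo) * sin(pi * u)^2)

  stance_foot <- function(tau, land) {
    # returns c(heel_x, heel_y, pitch)
    if (rec$heel_lift == "no_heel") {
      th <- -20
      toe <- c(land + Lf, ground)
      return(c(toe[1] - Lf * cos(th * pi / 180),
               toe[2] + Lf * sin(th * pi / 180), th))
    }
    if (rec$heel_lift == "no_forefoot") return(c(land, ground, 15))
    if (tau < settle) {
      th <- theta_c * 0.5 * (1 + cos(pi * tau / settle))
      if (theta_c >= 0) return(c(land, ground, th))
      toe <- c(land + Lf, ground)
      return(c(toe[1] - Lf * cos(th * pi / 180),
               toe[2] + Lf * sin(th * pi / 180), th))
    }
    if (tau < hl_ph || rec$clearance == "none") return(c(land, ground, 0))
    w <- (tau - hl_ph) / (duty - hl_ph)
    th <- theta_po * sin(0.5 * pi * w)
    toe <- c(land + Lf, ground)
    c(toe[1] - Lf * cos(th * pi / 180), toe[2] + Lf * sin(th * pi / 180), th)
  }

  leg_traj <- function(strikes, lands) {
    heel <- matrix(NA_real_, N, 2); pitch <- numeric(N)
    for (t in seq_len(N)) {
      k <- max(which(strikes <= t))
      tau <- (t - strikes[k]) / P
      if (tau < duty) {
        hp <- stance_foot(tau, lands[k])
        heel[t, ] <- hp[1:2]; pitch[t] <- hp[3]
      } else {
        h0 <- stance_foot(duty - 1e-9, lands[k])
        h1 <- stance_foot(0, lands[k + 1])
        th1 <- h1[3]
        w <- (tau - duty) / (1 - duty)
        lift0 <- ground - h0[2]; lift1 <- ground - h1[2]
        lift <- lift0 * (1 - w) + lift1 * w + clear_px * sin(pi * w)
        # forward progress: constant velocity, decelerating over the last
        # 15% of swing to 1.5x the hip velocity so the heel still leads
        # the pelvis until touchdown (keeps the strike signal maximal at
        # the touchdown frame)
        dx_tot <- h1[1] - h0[1]
        Tsw <- (1 - duty) * P
        v_end <- 1.5 * S / P
        v1 <- (dx_tot - v_end * 0.075 * Tsw) / (0.925 * Tsw)
        xw <- if (w <= 0.85) v1 * w * Tsw
              else {
                uu <- (w - 0.85) / 0.15
                v1 * 0.85 * Tsw + 0.15 * Tsw * (v1 * uu - (v1 - v_end) * uu^2 / 2)
              }
        heel[t, 1] <- h0[1] + xw
        heel[t, 2] <- ground - lift
        pitch[t] <- if (rec$clearance == "reduced") {
          drag <- -asin(min(0.97, max(-0.97, lift / Lf))) * 180 / pi
          s <- if (w <= 0.8) 0 else 0.5 * (1 - cos(pi * (w - 0.8) / 0.2))
          (1 - s) * drag + s * th1
        } else if (rec$clearance == "none")
          cos_interp(w, c(0, 0.3, 0.85, 1), c(h0[3], 0, 0, th1))
        else cos_interp(w, c(0, 0.5, 0.85, 1), c(h0[3], theta_mid, -8, th1))
      }
    }
    toe <- heel + Lf * cbind(cos(pitch * pi / 180), -sin(pitch * pi / 180))
    small <- heel + 0.86 * Lf * cbind(cos(pitch * pi / 180),
                                      -sin(pitch * pi / 180))
    ank <- heel + t(vapply(seq_len(N), function(t)
      rot_off(ank_f, -ank_u, pitch[t]), numeric(2)))
    list(heel = heel, toe = toe, small = small, ankle = ank, pitch = pitch)
  }

  legs <- list(right = leg_traj(strike_list$right, land_list$right),
               left = leg_traj(strike_list$left, land_list$left))

  # assemble keypoints (generated left-to-right; mirrored later if needed)
  x <- matrix(NA_real_, N, N_KEYPOINTS); y <- matrix(NA_real_, N, N_KEYPOINTS)
  put <- function(id, px, py) {
    x[, id + 1L] <<- px; y[, id + 1L] <<- py
  }
  lean <- rec$trunk_lean_deg * pi / 180
  neck_x <- hip_x + trunk * sin(lean); neck_y <- hip_y - trunk * cos(lean)
  put(KP_MIDHIP, hip_x, hip_y)
  put(KP_NECK, neck_x, neck_y)
  put(KP_NOSE, neck_x + 25 * sc, neck_y - 80 * sc)
  # face cluster
  put(15L, neck_x + 30 * sc, neck_y - 88 * sc)
  put(16L, neck_x + 18 * sc, neck_y - 88 * sc)
  put(17L, neck_x + 12 * sc, neck_y - 80 * sc)
  put(18L, neck_x + 4 * sc, neck_y - 80 * sc)
  # arms hang by the trunk with a small static offset
  for (ids in list(c(2L, 3L, 4L, +6), c(5L, 6L, 7L, -6))) {
    sx <- ids[4] * sc
    put(ids[1], neck_x + sx, neck_y + 15 * sc)
    put(ids[2], neck_x + sx, neck_y + 15 * sc + 110 * sc)
    put(ids[3], neck_x + sx, neck_y + 15 * sc + 200 * sc)
  }
  hw_eff <- 60 * sc * sin(rec$pelvic_rotation_deg * pi / 180)

  angles_true <- list()
  for (side in c("left", "right")) {
    lg <- legs[[side]]
    k <- kp_side(side)
    hipx <- hip_x + if (side == "right") hw_eff else -hw_eff
    knee <- matrix(NA_real_, N, 2)
    thigh_deg <- knee_deg <- numeric(N)
    for (t in seq_len(N)) {
      ik <- ik_knee(hipx[t], hip_y[t], lg$ankle[t, 1], lg$ankle[t, 2], L1, L2)
      knee[t, ] <- ik$knee; thigh_deg[t] <- ik$thigh_deg
      knee_deg[t] <- ik$knee_deg
    }
    put(k$hip, hipx, hip_y)
    put(k$knee, knee[, 1], knee[, 2])
    put(k$ankle, lg$ankle[, 1], lg$ankle[, 2])
    put(k$heel, lg$heel[, 1], lg$heel[, 2])
    put(k$bigtoe, lg$toe[, 1], lg$toe[, 2])
    put(k$smalltoe, lg$small[, 1], lg$small[, 2])
    sigma <- atan2(lg$ankle[, 1] - knee[, 1], lg$ankle[, 2] - knee[, 2]) *
      180 / pi
    angles_true[[side]] <- list(hip = thigh_deg + rec$trunk_lean_deg,
                                knee = knee_deg,
                                dorsiflexion = lg$pitch - sigma)
  }

  in_range <- function(f) f[f >= 3 & f <= N - 2]
  gt_ev <- function(frames, side, kind)
    data.frame(frame = frames, side = rep(side, length(frames)),
               kind = rep(kind, length(frames)), stringsAsFactors = FALSE)
  strikes <- rbind(
    gt_ev(in_range(strike_list$left), "left", "foot_strike"),
    gt_ev(in_range(strike_list$right), "right", "foot_strike"))
  offs <- rbind(
    gt_ev(in_range(strike_list$left + round(duty * P)), "left", "foot_off"),
    gt_ev(in_range(strike_list$right + round(duty * P)), "right", "foot_off"))
  # mid-midstance: toe-x crossing between consecutive opposite strikes
  allst <- strikes[order(strikes$frame), ]
  mms <- NULL
  dxt <- legs$left$toe[, 1] - legs$right$toe[, 1]
  if (nrow(allst) >= 2) {
    for (i in seq_len(nrow(allst) - 1)) {
      f1 <- allst$frame[i]; f2 <- allst$frame[i + 1]
      if (allst$side[i] == allst$side[i + 1] || f2 - f1 < 4) next
      f <- (f1:f2)[which.min(abs(dxt[f1:f2]))]
      mms <- rbind(mms, gt_ev(f, allst$side[i], "mid_midstance"))
    }
  }

  list(x = x, y = y, N = N,
       truth = list(strikes = strikes, offs = offs, mid_midstance = mms,
                    angles = angles_true, stride_period = P))
}

synth_coronal <- function(rec) {
  sc <- rec$scale
  P <- round(2 * rec$fs * 60 / rec$cadence)
  duty <- 0.6
  f_px <- 2000; cx <- 960; cy <- 380
  trunk3 <- 300 * sc
  leg_h <- 330 * sc
  ground_y3 <- trunk3 + leg_h          # below camera (neck) level
  stride_z <- 360 * sc
  step_w <- 25 * sc; hip_w <- 60 * sc
  Lf3 <- 90 * sc
  # modest swing clearance: in this projection the toe-distance signal is
  # carried by depth separation, which excessive lift would mask
  clear3 <- 12 * sc
  rho <- rec$foot_rotation_deg * pi / 180
  beta <- rec$pelvic_obliquity_deg * pi / 180
  sway_deg <- 2 + rec$trunk_shift_deg   # physiologic sway toward stance side

  toward <- rec$direction == "toward_camera"
  dz <- if (toward) -1 else 1
  t_R0 <- 31
  N <- t_R0 + rec$n_strides * P + 30
  vz <- stride_z / P
  z0 <- if (toward) 1300 + vz * N else 1300

  body_z <- z0 + dz * vz * seq_len(N)
  strike_list <- list(right = t_R0 + (-1:(rec$n_strides + 1)) * P,
                      left = t_R0 + round(P / 2) + (-1:(rec$n_strides + 1)) * P)
  # foot z at each landing: half a stride ahead of the body
  land_z <- lapply(strike_list, function(st)
    z0 + dz * (vz * st + stride_z / 4))

  foot_z_traj <- function(strikes, lands) {
    z <- numeric(N); lift <- numeric(N)
    for (t in seq_len(N)) {
      k <- max(which(strikes <= t))
      tau <- (t - strikes[k]) / P
      if (tau < duty) { z[t] <- lands[k]; lift[t] <- 0 }
      else {
        w <- (tau - duty) / (1 - duty)
        z[t] <- lands[k] + (lands[k + 1] - lands[k]) * w
        lift[t] <- clear3 * sin(pi * w)
      }
    }
    list(z = z, lift = lift)
  }
  feet <- list(right = foot_z_traj(strike_list$right, land_z$right),
               left = foot_z_traj(strike_list$left, land_z$left))

  x <- matrix(NA_real_, N, N_KEYPOINTS); y <- matrix(NA_real_, N, N_KEYPOINTS)
  proj <- function(X3, Y3, Z3) list(x = cx + f_px * X3 / Z3,
                                    y = cy + f_px * Y3 / Z3)
  put <- function(id, p) { x[, id + 1L] <<- p$x; y[, id + 1L] <<- p$y }

  hip_y3 <- trunk3
  # trunk sways toward the stance side (right foot is at +x facing the
  # camera); peaks near each mid-midstance
  lam <- sway_deg * pi / 180 * sin(2 * pi * (seq_len(N) - t_R0) / P)
  put(KP_MIDHIP, proj(0, hip_y3, body_z))
  neck <- proj(trunk3 * sin(lam), hip_y3 - trunk3 * cos(lam), body_z)
  put(KP_NECK, neck)
  put(KP_NOSE, proj(trunk3 * sin(lam), hip_y3 - trunk3 * cos(lam) - 50 * sc,
                    body_z - 10))
  put(15L, proj(trunk3 * sin(lam) + 8 * sc,
                hip_y3 - trunk3 * cos(lam) - 58 * sc, body_z - 10))
  put(16L, proj(trunk3 * sin(lam) - 8 * sc,
                hip_y3 - trunk3 * cos(lam) - 58 * sc, body_z - 10))
  put(17L, proj(trunk3 * sin(lam) + 16 * sc,
                hip_y3 - trunk3 * cos(lam) - 52 * sc, body_z))
  put(18L, proj(trunk3 * sin(lam) - 16 * sc,
                hip_y3 - trunk3 * cos(lam) - 52 * sc, body_z))
  for (ids in list(c(2L, 3L, 4L, +1), c(5L, 6L, 7L, -1))) {
    sx <- ids[4] * (hip_w + 15 * sc)
    put(ids[1], proj(sx, hip_y3 - trunk3 * 0.9, body_z))
    put(ids[2], proj(sx + ids[4] * 5 * sc, hip_y3 - trunk3 * 0.45, body_z))
    put(ids[3], proj(sx + ids[4] * 8 * sc, hip_y3, body_z))
  }
  # pelvic obliquity raises one hip
  put(KP_RHIP, proj(+hip_w, hip_y3 - hip_w * tan(beta), body_z))
  put(KP_LHIP, proj(-hip_w, hip_y3 + hip_w * tan(beta), body_z))

  for (side in c("left", "right")) {
    k <- kp_side(side)
    sgn <- if (side == "right") 1 else -1   # image-x side when facing camera
    ft <- feet[[side]]
    heel_y3 <- ground_y3 - ft$lift
    heel_x3 <- sgn * step_w
    toe_x3 <- heel_x3 + sgn * Lf3 * sin(rho)
    toe_z <- ft$z + dz * Lf3 * cos(rho)
    put(k$heel, proj(heel_x3, heel_y3, ft$z))
    put(k$bigtoe, proj(toe_x3, heel_y3, toe_z))
    put(k$smalltoe, proj(toe_x3 + sgn * 8 * sc, heel_y3 - 2 * sc,
                         toe_z - dz * 8 * sc))
    ank <- proj(heel_x3, heel_y3 - 28 * sc, ft$z - dz * 6 * sc)
    put(k$ankle, ank)
    put(k$knee, proj(heel_x3 * 0.9, (hip_y3 + (ground_y3 - 28 * sc)) / 2,
                     ft$z * 0.5 + body_z * 0.5 + dz * (-12 * sc)))
  }

  in_range <- function(f) f[f >= 3 & f <= N - 2]
  gt_ev <- function(frames, side, kind)
    data.frame(frame = frames, side = rep(side, length(frames)),
               kind = rep(kind, length(frames)), stringsAsFactors = FALSE)
  strikes <- rbind(
    gt_ev(in_range(strike_list$left), "left", "foot_strike"),
    gt_ev(in_range(strike_list$right), "right", "foot_strike"))
  allst <- strikes[order(strikes$frame), ]
  mms <- NULL
  dzf <- feet$left$z - feet$right$z
  if (nrow(allst) >= 2) {
    for (i in seq_len(nrow(allst) - 1)) {
      f1 <- allst$frame[i]; f2 <- allst$frame[i + 1]
      if (allst$side[i] == allst$side[i + 1] || f2 - f1 < 4) next
      f <- (f1:f2)[which.min(abs(dzf[f1:f2]))]
      mms <- rbind(mms, gt_ev(f, allst$side[i], "mid_midstance"))
    }
  }
  list(x = x, y = y, N = N,
       truth = list(strikes = strikes, offs = NULL, mid_midstance = mms,
                    angles = NULL, stride_period = P))
}

swap_sides_df <- function(d) {
  if (is.null(d)) return(d)
  d$side <- ifelse(d$side == "left", "right",
                   ifelse(d$side == "right", "left", d$side))
  d
}

#' Generate a synthetic walk with ground truth
#'
#' Runs the planar linked-segment walker defined by the recipe: feet
#' follow stance/swing trajectories anchored to the ground, the knee is
#' placed by two-link inverse kinematics from a translating, vertically
#' vaulting hip root, and the trunk, head and arms ride on top. The
#' coronal view is produced by pinhole projection of a walker moving
#' along the camera axis. Gaussian pixel noise and confidence-correlated
#' dropout are applied last; ground truth (event frames, true joint
#' angles, intended score categories) is recorded pre-noise.
#'
#' @param recipe A [gait_recipe()].
#' @return List with `seq` (a `pose_sequence`) and `truth` (ground-truth
#'   list: `strikes`, `offs`, `mid_midstance` data frames, per-side true
#'   `angles`, `intended` score categories, `stride_period`).
#' @export
generate_gait <- function(recipe) {
  stopifnot(inherits(recipe, "gait_recipe"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(recipe$seed)

  raw <- if (recipe$view == "sagittal") synth_sagittal(recipe)
         else synth_coronal(recipe)
  truth <- raw$truth
  truth$intended <- intended_scores(recipe)

  n <- raw$N
  conf <- matrix(stats::runif(n * N_KEYPOINTS, 0.55, 0.95), n, N_KEYPOINTS)
  x <- raw$x; y <- raw$y
  if (recipe$noise_sd > 0) {
    x <- x + stats::rnorm(n * N_KEYPOINTS, 0, recipe$noise_sd)
    y <- y + stats::rnorm(n * N_KEYPOINTS, 0, recipe$noise_sd)
  }
  if (recipe$dropout > 0) {
    drop <- matrix(stats::runif(n * N_KEYPOINTS) < recipe$dropout, n,
                   N_KEYPOINTS)
    conf[drop] <- stats::runif(sum(drop), 0, 0.09)
    x[drop] <- x[drop] + stats::rnorm(sum(drop), 0, 3 * max(recipe$noise_sd, 1))
    y[drop] <- y[drop] + stats::rnorm(sum(drop), 0, 3 * max(recipe$noise_sd, 1))
  }
  seq <- pose_sequence(x, y, conf, fs = recipe$fs, resolution = c(1920, 1080))

  if (recipe$direction == "right_to_left") {
    seq <- mirror_sequence(seq)
    truth$strikes <- swap_sides_df(truth$strikes)
    truth$offs <- swap_sides_df(truth$offs)
    truth$mid_midstance <- swap_sides_df(truth$mid_midstance)
    if (!is.null(truth$angles))
      truth$angles <- list(left = truth$angles$right,
                           right = truth$angles$left)
  }
  list(seq = seq, truth = truth)
}

# intended EVGS categories implied by the recipe's deviation switches
intended_scores <- function(rec) {
  out <- list()
  add <- function(param, ordinal, label)
    out[[length(out) + 1]] <<- data.frame(parameter = param,
                                          ordinal = as.integer(ordinal),
                                          label = label,
                                          stringsAsFactors = FALSE)
  if (rec$view == "sagittal") {
    # only claim an intended category for a parameter when no other
    # injected deviation physically entangles it (e.g. toe walking also
    # changes initial contact; dragging the feet suppresses heel lift)
    if (rec$heel_lift %in% c("normal", "early", "delayed"))
      add(1L, switch(rec$contact, heel = 0L, flat = 1L, toe = 2L),
          paste(rec$contact, "contact"))
    tl <- rec$trunk_lean_deg
    if (abs(tl) <= 5) add(16L, 0L, "normal")
    else if (tl > 15) add(16L, 2L, "marked forward lean")
    else if (tl > 5) add(16L, 1L, "moderate forward lean")
    else add(16L, 1L, "backward lean")
    if (rec$heel_lift == "normal")
      add(6L, switch(rec$clearance, full = 0L, reduced = 1L, none = 2L,
                     high = 1L),
          switch(rec$clearance, full = "full clearance",
                 reduced = "reduced clearance", none = "no clearance",
                 high = "high step"))
    if (rec$contact == "heel" && rec$clearance != "none")
      add(2L, switch(rec$heel_lift, normal = 0L, early = 1L, delayed = 1L,
                     no_heel = 2L, no_forefoot = 2L),
          switch(rec$heel_lift, normal = "normal", early = "early",
                 delayed = "delayed", no_heel = "no heel contact",
                 no_forefoot = "no forefoot contact"))
  } else {
    b <- abs(rec$pelvic_obliquity_deg)
    add(14L, if (b < 5) 0L else if (b < 15) 1L else 2L,
        if (b < 5) "normal" else if (b < 15) "moderate" else "marked")
    # peak trunk sway toward the stance side at mid-midstance: base 2
    # degrees of physiologic sway plus the injected shift, sampled near
    # the sway peak (sin(0.6 * pi) of the sway cycle)
    ts <- (2 + rec$trunk_shift_deg) * sin(0.6 * pi)
    if (ts < 0) add(17L, 1L, "reduced")
    else if (ts > 15) add(17L, 2L, "marked")
    else if (ts > 5) add(17L, 1L, "moderate")
    else add(17L, 0L, "normal")
  }
  do.call(rbind, out)
}

#' Write the fixture suite of reference recipes
#'
#' One fixture per gait-set family (nine sagittal, five coronal), each a
#' directory of per-frame BODY25 JSON files plus `ground_truth.json` and
#' `recipe.json`.
#'
#' @param out_dir Output directory.
#' @param n_strides Strides per fixture (small default keeps it quick).
#' @return Invisibly, a named list of fixture directories.
#' @export
write_fixture_suite <- function(out_dir, n_strides = 3) {
  recipes <- list(
    sagittal_healthy = gait_recipe("sagittal", seed = 101, n_strides = n_strides),
    sagittal_hip = gait_recipe("sagittal", seed = 102, n_strides = n_strides,
                               crouch_deg = 12),
    sagittal_knee = gait_recipe("sagittal", seed = 103, n_strides = n_strides,
                                crouch_deg = 20),
    sagittal_ankle = gait_recipe("sagittal", seed = 104, n_strides = n_strides,
                                 heel_lift = "no_heel"),
    sagittal_trunk = gait_recipe("sagittal", seed = 105, n_strides = n_strides,
                                 trunk_lean_deg = 10),
    sagittal_pelvis = gait_recipe("sagittal", seed = 106, n_strides = n_strides,
                                  pelvic_rotation_deg = 12),
    sagittal_foot_position = gait_recipe("sagittal", seed = 107,
                                         n_strides = n_strides,
                                         contact = "toe"),
    sagittal_heel_lift = gait_recipe("sagittal", seed = 108,
                                     n_strides = n_strides,
                                     heel_lift = "early"),
    sagittal_foot_clearance = gait_recipe("sagittal", seed = 109,
                                          n_strides = n_strides,
                                          clearance = "reduced"),
    coronal_healthy = gait_recipe("coronal", seed = 110, n_strides = n_strides),
    coronal_knee = gait_recipe("coronal", seed = 111, n_strides = n_strides),
    coronal_trunk = gait_recipe("coronal", seed = 112, n_strides = n_strides,
                                trunk_shift_deg = 10),
    coronal_foot = gait_recipe("coronal", seed = 113, n_strides = n_strides,
                               foot_rotation_deg = 30),
    coronal_pelvis = gait_recipe("coronal", seed = 114, n_strides = n_strides,
                                 pelvic_obliquity_deg = 8))
  dirs <- list()
  for (nm in names(recipes)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    g <- generate_gait(recipes[[nm]])
    write_body25_json(g$seq, file.path(d, "keypoints"))
    jsonlite::write_json(g$truth, file.path(d, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(unclass(recipes[[nm]]), file.path(d, "recipe.json"),
                         auto_unbox = TRUE, digits = NA)
    dirs[[nm]] <- d
  }
  invisible(dirs)
}
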