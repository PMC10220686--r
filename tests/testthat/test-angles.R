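# Independent oracle: unsigned angle between vectors via acos of the
# normalized dot product, signed by the z cross product. Distinct
# numerics from the atan2 implementation under test.
oracle_angle <- function(u, v) {
  cu <- u / sqrt(sum(u^2)); cv <- v / sqrt(sum(v^2))
  a <- acos(pmin(1, pmax(-1, sum(cu * cv)))) * 180 / pi
  s <- sign(u[1] * v[2] - u[2] * v[1])
  if (s == 0) s <- 1
  a * s
}

rand_pt <- function() stats::runif(2, -500, 500)

test_that("hip angle is the signed trunk-thigh angle", {
  # neutral standing: thigh parallel to trunk
  s <- one_frame(`1` = c(0, 0), `8` = c(0, 100), `9` = c(0, 100),
                 `10` = c(0, 200))
  expect_equal(hip_angle(s, "right", "left_to_right")[1], 0, tolerance = 1e-12)
  # trunk vertical, thigh 45 degrees from horizontal, knee anterior
  s2 <- one_frame(`1` = c(0, 0), `8` = c(0, 100), `9` = c(0, 100),
                  `10` = c(100, 200))
  expect_equal(hip_angle(s2, "right", "left_to_right")[1], 45,
               tolerance = 1e-9)
  # flexion is positive regardless of walking direction
  s3 <- one_frame(`1` = c(0, 0), `8` = c(0, 100), `9` = c(0, 100),
                  `10` = c(-100, 200))
  expect_equal(hip_angle(s3, "right", "right_to_left")[1], 45,
               tolerance = 1e-9)
  # rigid rotation leaves the trunk-relative angle unchanged
  set.seed(7)
  for (i in 1:20) {
    th <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    pts <- list(`1` = c(0, 0), `8` = c(0, 100), `9` = c(5, 102),
                `10` = c(60, 190))
    rot <- lapply(pts, function(p) as.numeric(R %*% p))
    a0 <- hip_angle(do.call(one_frame, pts), "right", "left_to_right")[1]
    a1 <- hip_angle(do.call(one_frame, rot), "right", "left_to_right")[1]
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("knee angle matches the slope formula off the vertical and the
           vector oracle everywhere", {
  # collinear: zero flexion
  s <- one_frame(`9` = c(0, 0), `10` = c(0, 100), `11` = c(0, 200))
  expect_equal(knee_angle(s, "right", "left_to_right")[1], 0,
               tolerance = 1e-12)
  # thigh slope 0, shank slope 1: arctan((m3-m2)/(1+m3*m2)) = 45
  s2 <- one_frame(`9` = c(0, 0), `10` = c(100, 0), `11` = c(200, 100))
  expect_equal(abs(knee_angle(s2, "right", "left_to_right")[1]), 45,
               tolerance = 1e-9)
  # perpendicular thigh and shank: exactly 90
  s3 <- one_frame(`9` = c(0, 0), `10` = c(0, 100), `11` = c(-100, 100))
  expect_equal(abs(knee_angle(s3, "right", "left_to_right")[1]), 90,
               tolerance = 1e-12)
  # translation, rotation and scale invariance
  set.seed(8)
  base <- list(`9` = c(10, 20), `10` = c(40, 130), `11` = c(20, 240))
  a0 <- knee_angle(do.call(one_frame, base), "left", "left_to_right")[1]
  for (i in 1:10) {
    th <- stats::runif(1, -pi, pi); k <- stats::runif(1, 0.1, 5)
    R <- k * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- stats::runif(2, -300, 300)
    mv <- lapply(base, function(p) as.numeric(R %*% p + tr))
    expect_equal(knee_angle(do.call(one_frame, mv), "left",
                            "left_to_right")[1], a0, tolerance = 1e-9)
  }
})

test_that("ankle angle reads 90 at neutral with dorsiflexion positive", {
  # foot perpendicular to a vertical shank
  s <- one_frame(`10` = c(0, 0), `11` = c(0, 100), `24` = c(0, 120),
                 `22` = c(60, 120), `23` = c(55, 120))
  expect_equal(ankle_angle(s, "right", "left_to_right")[1], 90,
               tolerance = 1e-9)
  # toes toward the shin increase the angle
  s2 <- one_frame(`10` = c(0, 0), `11` = c(0, 100), `24` = c(0, 120),
                  `22` = c(58, 105), `23` = c(58, 105))
  expect_gt(ankle_angle(s2, "right", "left_to_right")[1], 90)
  # shank slope 1, foot slope 0
  s3 <- one_frame(`10` = c(0, 0), `11` = c(100, 100), `24` = c(100, 130),
                  `22` = c(160, 130), `23` = c(160, 130))
  expect_equal(abs(dorsiflexion_angle(s3, "right", "left_to_right")[1]), 45,
               tolerance = 1e-9)
  # scale invariance
  s4 <- one_frame(`10` = c(0, 0), `11` = c(200, 200), `24` = c(200, 260),
                  `22` = c(320, 260), `23` = c(320, 260))
  expect_equal(ankle_angle(s4, "right", "left_to_right")[1],
               ankle_angle(s3, "right", "left_to_right")[1], tolerance = 1e-9)
})

test_that("all joint angles agree with the vector oracle on random
           placements including vertical segments", {
  set.seed(99)
  n_bad <- 0
  for (i in 1:2500) {
    neck <- rand_pt(); hip <- rand_pt(); knee <- rand_pt(); ank <- rand_pt()
    heel <- rand_pt(); bt <- rand_pt(); st <- bt
    # force exactly vertical segments in a fifth of the cases, where the
    # printed slope formulas would divide by zero
    if (i %% 5 == 0) { knee[1] <- hip[1]; ank[1] <- knee[1] }
    if (max(abs(hip - knee)) < 1 || max(abs(knee - ank)) < 1 ||
        max(abs(neck - hip)) < 1 || max(abs((bt + st) / 2 - heel)) < 1) next
    s <- one_frame(`1` = neck, `8` = hip, `9` = hip, `10` = knee,
                   `11` = ank, `24` = heel, `22` = bt, `23` = st)
    got_hip <- hip_angle(s, "right", "left_to_right")[1]
    want_hip <- -oracle_angle(hip - neck, knee - hip)
    expect_lt(ang_diff(got_hip, want_hip), 1e-9)
    got_knee <- knee_angle(s, "right", "left_to_right")[1]
    want_knee <- oracle_angle(knee - hip, ank - knee)
    expect_lt(ang_diff(got_knee, want_knee), 1e-9)
    got_ank <- ankle_angle(s, "right", "left_to_right")[1]
    want_ank <- -oracle_angle(ank - knee, (bt + st) / 2 - heel)
    expect_lt(ang_diff(got_ank, want_ank), 1e-9)
    n_bad <- n_bad + 1
  }
  expect_gt(n_bad, 2000)
})

test_that("segment-axis angles follow the stated sign conventions", {
  expect_equal(segment_axis_angle(0, 0, 100, 0, "image_x"), 0)
  expect_equal(segment_axis_angle(0, 0, 0, 100, "image_y"), 0)
  # forward endpoint higher in the image (smaller y): positive vs x-axis
  expect_equal(segment_axis_angle(0, 0, 100, -100, "image_x"), 45,
               tolerance = 1e-12)
  expect_equal(segment_axis_angle(0, 0, 100, 100, "image_x"), -45,
               tolerance = 1e-12)
  # direction of travel along the segment does not flip the x-axis sign
  expect_equal(segment_axis_angle(100, -100, 0, 0, "image_x"), -45,
               tolerance = 1e-12)
  # vertical segment vs x-axis: exactly +/-90
  expect_equal(segment_axis_angle(0, 0, 0, -50, "image_x"), 90)
  expect_error(segment_axis_angle(5, 5, 5, 5, "image_x"), "coincident")
})
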