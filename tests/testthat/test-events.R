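test_that("inter-toe distance is a plain Euclidean distance", {
  s <- one_frame(`19` = c(0, 0), `22` = c(3, 4))
  expect_equal(inter_toe_distance(s, 1), 5)
  s2 <- one_frame(`19` = c(7, 7), `22` = c(7, 7))
  expect_equal(inter_toe_distance(s2, 1), 0)
  # rigid rotation invariance
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p1 <- c(12, 34); p2 <- c(-5, 80)
  sr <- one_frame(`19` = as.numeric(R %*% p1), `22` = as.numeric(R %*% p2))
  s0 <- one_frame(`19` = p1, `22` = p2)
  expect_equal(inter_toe_distance(sr, 1), inter_toe_distance(s0, 1),
               tolerance = 1e-9)
  s3 <- one_frame(`19` = c(0, 0))
  expect_true(is.na(inter_toe_distance(s3, 1)))
})

test_that("a standing pose yields no events", {
  n <- 200
  s <- toy_sequence(list(`8` = cbind(500, 400),
                         `21` = cbind(480, 900), `24` = cbind(520, 900),
                         `19` = cbind(530, 905), `22` = cbind(570, 905)),
                    n = n)
  ev <- detect_events(s, "sagittal", "left_to_right")
  expect_identical(nrow(ev), 0L)
})

test_that("strikes, offs and mid-midstances match generator truth at zero noise", {
  g <- quick_walk(seed = 31)
  pre <- preprocess(g$seq)
  ev <- detect_events(pre, "sagittal", "left_to_right")
  for (tt in list(g$truth$strikes, g$truth$offs, g$truth$mid_midstance)) {
    h <- event_hits(ev, tt, tol = 2)
    expect_identical(h[["hit"]], h[["total"]])
  }
  # strike of a foot precedes that foot's next off by > 40% of the stride
  for (side in c("left", "right")) {
    st <- sort(ev$frame[ev$kind == "foot_strike" & ev$side == side])
    of <- sort(ev$frame[ev$kind == "foot_off" & ev$side == side])
    for (s in st) {
      nxt <- of[of > s]
      if (length(nxt))
        expect_gt(nxt[1] - s, 0.4 * g$truth$stride_period)
    }
  }
})

test_that("mirroring swaps event sides but keeps frames", {
  g <- quick_walk(seed = 32)
  pre <- preprocess(g$seq)
  ev <- detect_events(pre, "sagittal", "left_to_right")
  evm <- detect_events(preprocess(mirror_sequence(g$seq)), "sagittal",
                       "right_to_left")
  for (kind in c("foot_strike", "foot_off")) {
    for (side in c("left", "right")) {
      a <- sort(ev$frame[ev$kind == kind & ev$side == side])
      b <- sort(evm$frame[evm$kind == kind &
                            evm$side == setdiff(c("left", "right"), side)])
      expect_equal(a, b)
    }
  }
})

test_that("same-kind same-side events respect the minimum separation", {
  g <- quick_walk(seed = 33, noise_sd = 2)
  pre <- preprocess(g$seq)
  ev <- detect_events(pre, "sagittal", "left_to_right")
  min_sep <- 0.4 * g$seq$fs
  for (kind in unique(ev$kind)) for (side in c("left", "right")) {
    fr <- sort(ev$frame[ev$kind == kind & !is.na(ev$side) & ev$side == side])
    if (length(fr) > 1) expect_true(all(diff(fr) >= min_sep))
  }
})

test_that("stride segmentation pairs consecutive same-side strikes and
           attaches contained events", {
  ev <- data.frame(
    frame = c(60, 80, 90, 92, 120),
    side = c("left", "right", "right", "left", "left"),
    kind = c("foot_strike", "foot_off", "foot_strike", "mid_midstance",
             "foot_strike"),
    stringsAsFactors = FALSE)
  st <- segment_strides(ev)
  expect_length(st, 1L)
  expect_identical(st[[1]]$side, "left")
  expect_identical(st[[1]]$start, 60)
  expect_identical(st[[1]]$end, 120)
  expect_true(all(c("foot_off", "mid_midstance") %in% st[[1]]$events$kind))

  ev2 <- data.frame(frame = c(60, 120, 180), side = "left",
                    kind = "foot_strike", stringsAsFactors = FALSE)
  expect_length(segment_strides(ev2), 2L)

  ev3 <- data.frame(frame = 60, side = "left", kind = "foot_strike",
                    stringsAsFactors = FALSE)
  expect_error(segment_strides(ev3), "no strides")
})

test_that("stride counts on a synthetic walk are within two of truth", {
  g <- generate_gait(gait_recipe("sagittal", seed = 34, n_strides = 5))
  pre <- preprocess(g$seq)
  ev <- detect_events(pre, "sagittal", "left_to_right")
  st <- segment_strides(ev)
  n_true <- table(g$truth$strikes$side) - 1
  cnt <- stride_counts(st)
  expect_lte(abs(cnt[["left"]] - n_true[["left"]]), 2)
  expect_lte(abs(cnt[["right"]] - n_true[["right"]]), 2)
})
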