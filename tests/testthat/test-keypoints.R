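test_that("BODY25 JSON round-trips bit-exactly and maps (0,0,0) to missing", {
  g <- quick_walk(seed = 11, dropout = 0.03)
  dir <- file.path(tempdir(), "rt_json")
  unlink(dir, recursive = TRUE)
  write_body25_json(gate_confidence(g$seq), dir)
  back <- read_body25_json(dir)
  orig <- gate_confidence(g$seq)
  expect_identical(dim(back$x), dim(orig$x))
  expect_equal(back$x, orig$x, tolerance = 0)
  expect_equal(back$y, orig$y, tolerance = 0)
  # gated keypoints came back as missing, not as coordinates at the origin
  expect_true(all(is.na(back$x[is.na(orig$x)])))
  expect_false(any(back$x == 0 & back$y == 0, na.rm = TRUE))
})

test_that("multi-person and unusable sequences are rejected", {
  dir <- file.path(tempdir(), "bad_json")
  unlink(dir, recursive = TRUE); dir.create(dir)
  person <- list(pose_keypoints_2d = rep(c(1, 2, 0.9), 25))
  jsonlite::write_json(list(people = list(person, person)),
                       file.path(dir, "f_000000_keypoints.json"),
                       auto_unbox = TRUE)
  expect_error(read_body25_json(dir), "multi-person")

  dir2 <- file.path(tempdir(), "empty_json")
  unlink(dir2, recursive = TRUE); dir.create(dir2)
  for (i in 1:3)
    jsonlite::write_json(list(people = list()),
                         file.path(dir2, sprintf("f_%06d_keypoints.json", i)),
                         auto_unbox = TRUE)
  jsonlite::write_json(list(people = list(person)),
                       file.path(dir2, "f_000004_keypoints.json"),
                       auto_unbox = TRUE)
  expect_error(read_body25_json(dir2), "unusable")
})

test_that("keypoint CSV round-trips", {
  g <- quick_walk(seed = 12)
  path <- tempfile(fileext = ".csv")
  write_keypoints_csv(g$seq, path)
  back <- read_keypoints_csv(path)
  expect_equal(back$x, g$seq$x)
  expect_equal(back$conf, g$seq$conf)
})

test_that("confidence gate drops strictly-below-threshold keypoints only", {
  x <- matrix(100, 4, 25); y <- matrix(200, 4, 25)
  conf <- matrix(1, 4, 25)
  conf[1, 1] <- 0.05   # below
  conf[2, 2] <- 0.10   # exactly at threshold: kept
  conf[3, 3] <- 0.099999
  seq <- pose_sequence(x, y, conf)
  out <- gate_confidence(seq, 0.10)
  expect_true(is.na(out$x[1, 1]))
  expect_false(is.na(out$x[2, 2]))
  expect_true(is.na(out$x[3, 3]))
  expect_identical(n_frames(out), 4L)
  # all confident: identity
  out2 <- gate_confidence(pose_sequence(x, y, matrix(1, 4, 25)))
  expect_equal(out2$x, x)
  # inclusive variant drops the boundary value
  expect_true(is.na(gate_confidence(seq, 0.10, inclusive = TRUE)$x[2, 2]))
})

test_that("gap interpolation reproduces an exact cubic and refuses long/edge gaps", {
  t <- 1:40
  cubic <- 0.002 * t^3 - 0.1 * t^2 + 3 * t + 7
  x <- matrix(NA_real_, 40, 25)
  y <- matrix(NA_real_, 40, 25)
  x[, 1] <- cubic; y[, 1] <- rev(cubic)
  gap3 <- 10:12; gap6 <- 25:30
  x[gap3, 1] <- NA; x[gap6, 1] <- NA
  x[1:2, 1] <- NA                     # leading gap stays missing
  y[gap3, 1] <- NA
  seq <- pose_sequence(x, y)
  out <- interpolate_gaps(seq, max_gap = 5)
  expect_equal(out$x[gap3, 1], cubic[gap3], tolerance = 1e-6)
  expect_equal(out$y[gap3, 1], rev(cubic)[gap3], tolerance = 1e-6)
  expect_true(all(is.na(out$x[gap6, 1])))
  expect_true(all(is.na(out$x[1:2, 1])))
  # idempotent
  out2 <- interpolate_gaps(out, max_gap = 5)
  expect_identical(out2$x, out$x)
  # no gaps: identity
  full <- pose_sequence(matrix(1:40, 40, 25), matrix(1, 40, 25))
  expect_equal(interpolate_gaps(full)$x, full$x)
  # fewer than 4 present samples: untouched, with a warning
  sparse <- matrix(NA_real_, 40, 25)
  sparse[c(1, 20, 40), 2] <- 5
  expect_warning(interpolate_gaps(pose_sequence(sparse, sparse)),
                 "fewer than 4")
})

test_that("zero-phase smoothing preserves DC, is linear, and matches the
           Butterworth magnitude response", {
  n <- 600; fs <- 60
  const <- pose_sequence(matrix(5, n, 25), matrix(-3, n, 25), fs = fs)
  out <- smooth_trajectories(const)
  expect_equal(out$x[, 1], rep(5, n), tolerance = 1e-9)

  # dual-pass attenuation of a 25 Hz tone equals |H(f)|^2 of the
  # bilinear-transform Butterworth prototype (independent closed form)
  f0 <- 25; fc <- 12; ord <- 2
  t <- seq_len(n)
  tone <- sin(2 * pi * f0 * t / fs)
  x <- matrix(0, n, 25); x[, 1] <- 1000 + 100 * tone
  seqt <- pose_sequence(x, x)
  sm <- smooth_trajectories(seqt, cutoff = fc, order = ord)
  mid <- 150:450
  # project the filtered midsection back onto the tone
  resp <- 2 * mean((sm$x[mid, 1] - 1000) / 100 * tone[mid])
  ratio <- tan(pi * f0 / fs) / tan(pi * fc / fs)
  expected <- (1 / (1 + ratio^(2 * ord)))   # squared single-pass magnitude
  expect_lt(abs(resp - expected), 0.05 * expected + 5e-6)

  # linearity
  set.seed(42)
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  mk <- function(v) pose_sequence(matrix(v, n, 25), matrix(0, n, 25))
  sab <- smooth_trajectories(mk(a + b))$x[, 1]
  sa <- smooth_trajectories(mk(a))$x[, 1]
  sb <- smooth_trajectories(mk(b))$x[, 1]
  expect_equal(sab, sa + sb, tolerance = 1e-9)

  # mean preservation on a long stationary segment
  set.seed(43)
  v <- 500 + stats::rnorm(n)
  sm2 <- smooth_trajectories(mk(v))$x[, 1]
  expect_lt(abs(mean(sm2) - mean(v)) / abs(mean(v)), 0.001)

  expect_error(smooth_trajectories(const, cutoff = 30), "cutoff")
})

test_that("trunk length is the KP1-KP8 distance and propagates missingness", {
  s <- one_frame(`1` = c(0, 0), `8` = c(0, 100))
  expect_equal(trunk_length(s, 1), 100)
  s2 <- one_frame(`1` = c(0, 0), `8` = c(3, 4))
  expect_equal(trunk_length(s2, 1), 5)
  s3 <- one_frame(`8` = c(3, 4))
  expect_true(is.na(trunk_length(s3, 1)))
})
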