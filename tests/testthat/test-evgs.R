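test_that("initial contact thresholds classify heel, flat and toe contact", {
  expect_identical(score_initial_contact(25)$label, "heel contact")
  expect_identical(score_initial_contact(25)$ordinal, 0L)
  expect_identical(score_initial_contact(10)$label, "flat foot contact")
  expect_identical(score_initial_contact(10)$ordinal, 1L)
  expect_identical(score_initial_contact(-5)$label, "toe contact")
  expect_identical(score_initial_contact(-5)$ordinal, 2L)
  # boundaries: 0 and 20 both belong to flat foot
  expect_identical(score_initial_contact(0)$label, "flat foot contact")
  expect_identical(score_initial_contact(20)$label, "flat foot contact")
  expect_false(score_initial_contact(NA)$scorable)
})

test_that("sagittal trunk bands: vertical-to-5 normal, 6-15 forward moderate,
           beyond 15 marked, backward beyond 5 moderate", {
  expect_identical(score_trunk_sagittal(3)$ordinal, 0L)
  expect_identical(score_trunk_sagittal(10)$ordinal, 1L)
  expect_identical(score_trunk_sagittal(20)$ordinal, 2L)
  expect_identical(score_trunk_sagittal(-3)$ordinal, 0L)
  expect_identical(score_trunk_sagittal(-10)$ordinal, 1L)
  expect_identical(score_trunk_sagittal(-10)$label, "backward lean")
})

test_that("lateral trunk shift bands", {
  expect_identical(score_lateral_trunk_shift(2)$ordinal, 0L)
  expect_identical(score_lateral_trunk_shift(10)$label, "moderate")
  expect_identical(score_lateral_trunk_shift(20)$label, "marked")
  expect_identical(score_lateral_trunk_shift(20)$ordinal, 2L)
  expect_identical(score_lateral_trunk_shift(-2)$label, "reduced")
})

test_that("knee progression: +/-25 degree band", {
  expect_identical(score_knee_progression(0)$label, "normal")
  expect_identical(score_knee_progression(30)$label, "internal rotation")
  expect_identical(score_knee_progression(-30)$label, "external rotation")
})

test_that("peak hip flexion bands are anchored at 25-45 and 45-60", {
  b <- default_bands()$p13
  expect_identical(score_band(35, b)$ordinal, 0L)
  expect_identical(score_band(50, b)$ordinal, 1L)
  # lower-inclusive boundaries
  expect_identical(score_band(45, b)$ordinal, 1L)
  expect_identical(score_band(25, b)$ordinal, 0L)
})

test_that("band tables partition the line and are monotone in deviation", {
  for (nm in names(default_bands())) {
    b <- default_bands()[[nm]]
    # contiguous cover
    o <- order(b$lo)
    expect_equal(b$lo[o][-1], b$hi[o][-nrow(b)])
    expect_equal(b$lo[o][1], -Inf)
    expect_equal(b$hi[o][nrow(b)], Inf)
    # walking outward from the normal band never decreases the ordinal
    r0 <- b[o, ][which(b$ordinal[o] == 0)[1], ]
    lo0 <- if (is.finite(r0$lo)) r0$lo else r0$hi - 20
    hi0 <- if (is.finite(r0$hi)) r0$hi else lo0 + 20
    centre <- (lo0 + hi0) / 2
    up <- vapply(seq(centre, centre + 200, by = 1),
                 function(v) score_band(v, b)$ordinal, integer(1))
    dn <- vapply(seq(centre, centre - 200, by = -1),
                 function(v) score_band(v, b)$ordinal, integer(1))
    expect_true(all(diff(up) >= 0))
    expect_true(all(diff(dn) >= 0))
  }
})

test_that("heel lift timing logic", {
  # lift between feet-level frame and opposite strike: normal
  expect_identical(score_heel_lift(100, 90, 120)$label, "normal")
  expect_identical(score_heel_lift(100, 90, 120)$ordinal, 0L)
  expect_identical(score_heel_lift(85, 90, 120)$label, "early")
  expect_identical(score_heel_lift(125, 90, 120)$label, "delayed")
  expect_identical(score_heel_lift(NA, 90, 120)$label, "delayed")
  expect_identical(score_heel_lift(100, 90, 120, "toe_only")$label,
                   "no heel contact")
  expect_identical(score_heel_lift(100, 90, 120, "heel_only")$label,
                   "no forefoot contact")
  expect_false(score_heel_lift(100, NA, 120)$scorable)
})

test_that("foot clearance categories at the passing frame", {
  # y grows downward; stance foot on the ground at y = 900
  full <- score_foot_clearance(870, 860, 900, 900, 700)
  expect_identical(full$label, "full clearance")
  red <- score_foot_clearance(900, 860, 900, 900, 700)
  expect_identical(red$label, "reduced clearance")
  expect_identical(red$ordinal, 1L)
  none <- score_foot_clearance(899, 899, 900, 900, 700)
  expect_identical(none$label, "no clearance")
  expect_identical(none$ordinal, 2L)
  high <- score_foot_clearance(650, 640, 900, 900, 700)
  expect_identical(high$label, "high step")
  expect_false(score_foot_clearance(NA, 860, 900, 900, 700)$scorable)
})

test_that("per-video score is the most frequent stride score, ties worse", {
  expect_identical(evgait:::mode_worse(c(0L, 0L, 1L)), 0L)
  expect_identical(evgait:::mode_worse(c(0L, 1L)), 1L)
  expect_identical(evgait:::mode_worse(c(2L, 0L, 0L, 2L, 1L)), 2L)
  expect_true(is.na(evgait:::mode_worse(c(NA_integer_, NA_integer_))))
})

test_that("the report always carries 17 parameters per leg with reasons", {
  g <- quick_walk(seed = 41)
  rep <- run_pipeline(g$seq)
  for (side in c("left", "right")) {
    sub <- rep$scores[rep$scores$side == side, ]
    expect_identical(sort(sub$parameter), 1:17)
    # coronal parameters flagged, never silently scored
    cor <- sub[sub$parameter %in% c(4, 5, 8, 14, 17), ]
    expect_true(all(!cor$scorable))
    expect_true(all(grepl("view", cor$reason)))
  }
})

test_that("a noise-free normal walk scores 0 on all controllable parameters", {
  g <- quick_walk(seed = 42)
  rep <- run_pipeline(g$seq)
  sc <- rep$scores[rep$scores$scorable & rep$scores$parameter != 15, ]
  expect_true(all(sc$ordinal == 0))
  g2 <- generate_gait(gait_recipe("coronal", seed = 43, n_strides = 3))
  rep2 <- run_pipeline(g2$seq)
  sc2 <- rep2$scores[rep2$scores$scorable, ]
  expect_true(all(sc2$ordinal == 0))
})

test_that("mirroring a noise-free walk swaps left and right scores", {
  g <- quick_walk(seed = 44, clearance = "reduced")
  rep <- run_pipeline(g$seq)
  repm <- run_pipeline(mirror_sequence(g$seq))
  a <- rep$scores; b <- repm$scores
  for (p in unique(a$parameter)) {
    expect_identical(a$ordinal[a$parameter == p & a$side == "left"],
                     b$ordinal[b$parameter == p & b$side == "right"])
    expect_identical(a$ordinal[a$parameter == p & a$side == "right"],
                     b$ordinal[b$parameter == p & b$side == "left"])
  }
})
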