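# evgait

Automated Edinburgh Visual Gait Score (EVGS) from 2-D pose keypoints.

Observational gait analysis scores a walking video on ordinal scales by
eye. The EVGS is the most widely used such scale for children with
cerebral palsy: 17 parameters per leg covering trunk, pelvis, hip, knee
and ankle across the gait cycle, each scored 0 (normal), 1 (moderate
deviation) or 2 (marked deviation). Human scoring takes experienced
reviewers 20+ minutes per video. `evgait` computes the score
algorithmically from the per-frame 2-D keypoints that a pose-estimation
model (BODY25 layout: 25 keypoints × x, y, confidence at 60 Hz) extracts
from an ordinary handheld video. It is aimed at clinical-movement
researchers who already have keypoint output and want reproducible,
rule-based EVGS scoring plus the scaffolding to validate it.

## What it does

1. **Preprocessing** — keypoints below a 10% confidence gate are removed,
   dropout gaps of ≤ 5 frames are filled by cubic-spline interpolation,
   and trajectories are smoothed with a zero-phase dual-pass second-order
   Butterworth filter (12 Hz cut-off).
2. **View and direction** — the walk is classified sagittal vs coronal
   from the trunk-length (midshoulder–midhip) change between the first
   and last frames (99 px threshold at 1080 px image height), and the
   walking direction from the nose x-displacement (sagittal) or the
   trunk-length sign (coronal).
3. **Gait events** — coordinate-based (Zeni-style) detection: foot
   strikes at maxima of the heel-minus-pelvis forward distance, foot
   offs at maxima of the pelvis-minus-toe distance, and mid-midstance
   (the feet-passing instant) at minima of the inter-toe distance
   `d = √((x₂−x₁)² + (y₂−y₁)²)`. Strides are the intervals between
   consecutive same-foot strikes, with all contained events attached.
4. **Angles** — hip (thigh vs trunk axis, flexion positive), knee (thigh
   vs shank, flexion positive) and ankle (foot vs shank, 90° neutral,
   dorsiflexion positive), plus segment-vs-image-axis angles for trunk,
   hip line, foot axis and hindfoot. All angles are computed with
   direction-vector arctangents, which agree with the classical
   slope-difference formula `θ = arctan((m₂−m₁)/(1+m₁m₂))` off vertical
   segments and remain exact on them.
5. **Scoring** — each of the 17 parameters is measured per stride at its
   gait event or phase window and mapped through the scale's standard thresholds
   (e.g. initial contact: foot-axis angle > 20° heel, 0–20° flat, < 0°
   toe; peak hip flexion: 25–45° normal, 45–60° moderate) or documented,
   user-overridable band tables. The per-leg score is the most frequent
   per-stride score, ties resolving to the worse score.

A synthetic gait generator (`gait_recipe()` / `generate_gait()`) builds
BODY25 walks with known event frames, joint angles and intended EVGS
categories — including injectable deviations (trunk lean, toe contact,
reduced clearance, toe/heel walking, early/delayed heel lift, crouch,
pelvic obliquity, foot rotation) — so every stage is testable without
any video data. Evaluation helpers reproduce confusion-matrix metrics,
frame-discrepancy categories and score correlations.

## Worked example

```r
library(evgait)

g <- generate_gait(gait_recipe("sagittal", seed = 5, n_strides = 3))
report <- run_pipeline(g$seq)
report
```

```
<evgs_report> sagittal view, left_to_right; strides L=2 R=3
  left leg:
    #1  Initial contact                    0 (heel contact) [24.3]
    #2  Heel lift                          0 (normal) [130.0]
    #3  Max ankle dorsiflexion in stance   0 (normal) [21.1]
    #6  Foot clearance in swing            0 (full clearance) [20.7]
    #7  Max ankle dorsiflexion in swing    0 (normal) [20.6]
    #9  Peak knee extension in stance      0 (normal) [8.2]
    #10 Knee extension in terminal swing   0 (normal) [13.0]
    #11 Peak knee flexion in swing         0 (normal) [68.9]
    #12 Peak hip extension in stance       0 (normal) [1.7]
    #13 Peak hip flexion in swing          0 (normal) [42.1]
    #15 Pelvic rotation in midstance       2 (marked) [90.0]
    #16 Peak sagittal trunk position       0 (normal) [0.0]
  ...
```

Each line is one EVGS parameter: its final ordinal, categorical label
and the measured value behind it (degrees for angle parameters, the
lift frame for heel lift, pixel clearance for foot clearance). This
healthy synthetic walk scores 0 throughout; the one exception, #15,
illustrates a real limitation: in a sagittal projection the two hip
keypoints nearly coincide, so the hip-line surrogate for pelvic
rotation is uninformative and is flagged accordingly (see the methods
vignette). Coronal-only parameters (#4, #5, #8, #14, #17) are marked
not-applicable for a sagittal video rather than silently scored.

An injected deviation is recovered with its category:

```r
g <- generate_gait(gait_recipe("sagittal", seed = 3, trunk_lean_deg = 10))
r <- run_pipeline(g$seq)
r$scores[r$scores$parameter == 16, c("side", "ordinal", "label", "value")]
#>   side ordinal                 label value
#>   left       1 moderate forward lean    10
#>  right       1 moderate forward lean    10
```

Real keypoints are read with `read_body25_json("dir/of/frames/")` (the
per-frame `people[[1]]$pose_keypoints_2d` dialect) or
`read_keypoints_csv()`, and scored the same way with `run_pipeline()`.
The command line equivalent:

```sh
inst/cli/evgs score path/to/keypoints --width 1920 --height 1080 --json report.json
```

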