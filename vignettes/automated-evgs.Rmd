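---
title: "Methods: automated EVGS scoring from 2-D keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated EVGS scoring from 2-D keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evgait)
```

This vignette documents the model behind `evgait`, the tunable
parameters and their defaults, the design choices made where the
measurement rules leave things open, what the synthetic generator does and does
not emulate, and the package's known limitations.

## The pipeline and its assumptions

The scorer assumes a single person walking in a straight line, filmed
at a nominally fixed camera either from the side (sagittal) or from the
front/rear (coronal), with per-frame BODY25 keypoints (25 points ×
x px, y px, confidence; image origin top-left, y increasing downward;
default 60 Hz). Multi-person frames abort, and a sequence with no
person in more than half its frames is rejected as unusable — the two
failure modes that dominate markerless scoring in practice.

Stages: preprocessing → view/direction classification → gait-event
detection → stride segmentation → angle computation → per-stride
scoring → per-leg aggregation. Everything is deterministic given the
input and an `evgs_config()`.

## Preprocessing

* **Confidence gate** (`conf_threshold = 0.10`): keypoints with
  confidence strictly below 10% become missing. "Below" is read
  strictly, so a confidence of exactly 0.10 survives; `conf_gate_inclusive`
  flips that reading.
* **Gap filling** (`max_gap = 5` frames, 0.083 s at 60 Hz): interior
  dropouts up to five frames are filled per coordinate by a cubic
  spline (Forsythe–Malcolm–Moler end conditions, `stats::spline`),
  which reproduces an exactly-cubic trajectory to machine precision.
  Gaps touching either end of the sequence are never extrapolated —
  spline extrapolation is unstable — and downstream stages tolerate
  missing samples instead.
* **Smoothing** (`cutoff_hz = 12`, `filter_order = 2`): zero-phase
  dual-pass Butterworth low-pass. The forward–backward pass uses
  odd-reflection edge padding of `filter_padlen = 30` samples; with a
  second-order filter at 12/60 Hz this lets the start-up transient
  decay below 10⁻⁹ of the signal, so constants pass through unchanged.
  Each contiguous present segment is filtered independently; segments
  shorter than 3·(order+1) samples pass through with a warning, since
  reflection padding needs context on both sides.

## View and direction

Trunk length (midshoulder KP1 to midhip KP8) is nearly constant across
a sagittal walk but scales with distance to the camera in a coronal
walk. A sequence is sagittal when |Δ trunk length| between the first
and last frames with both trunk keypoints present is below
`view_threshold_px = 99`, rescaled by image height against the 1080 px
reference — pixel thresholds are resolution-bound, so the gate scales
with the frame. Coronal direction follows the sign of the change
(growing trunk = approaching). Sagittal direction follows the nose's
net x-displacement, with a midhip fallback (and warning) when the nose
is never detected, e.g. in a rear view misrouted to the sagittal
branch; a net displacement under 1 px is reported as ambiguous rather
than guessed.

## Gait events

Sagittal strikes and offs use pelvis-relative forward displacement with
the midhip (KP8) as the sacral surrogate: the strike signal is the
signed heel-minus-midhip x-distance (maxima = strikes), the off signal
the midhip-minus-big-toe distance (maxima = offs). Mid-midstance — the
feet-passing instant, simultaneously mid-midswing of the other leg —
is the minimum of the inter-toe distance; one configuration, two roles,
so no separate mid-midswing detector exists. Each minimum is attributed
to the stance side via the most recent preceding strike.

No standard peak-finder settings exist for coordinate-based event
detection, so the package fixes them explicitly: an extremum must be separated from its neighbour
by `peak_min_sep_s = 0.4` s (below any plausible stride period) and
have a prominence of at least `peak_prom_frac = 5%` of the signal
range; endpoints are never events and ties resolve to the earliest
frame. These two rules are what suppress the double-detection and
missed-detection failures that plague raw argmax approaches.

In the coronal view the per-side displacement signals are undefined;
stride boundaries are taken from inter-toe-distance maxima (the feet
are furthest apart in the image at touchdown) and mid-midstance from
its minima, with the striking side attributed to the leading foot
(closer to the camera when approaching, farther when receding).

## Angles

All joint angles are computed from direction vectors with two-argument
arctangents. The classical slope-difference formula
θ = arctan((m₂−m₁)/(1+m₁m₂)) defines the semantics and serves as the
test oracle off vertical segments, but divides by zero on them — and a
shank or trunk passes through vertical every gait cycle — so no slope
arithmetic appears in the implementation. The perpendicular-to-trunk
axis used by the hip angle is the true geometric perpendicular
(direction vector rotated 90°); a reciprocal-slope shortcut is not a
perpendicular and has no code path here. Sign conventions are enforced
by orienting segments proximal→distal and flipping per walking
direction: hip flexion (knee anterior) positive, knee flexion positive,
ankle dorsiflexion positive with the neutral foot-perpendicular-to-shank
reading at 90° (`dorsiflexion_angle()` subtracts the 90). Degrees use
180/π throughout.

## Scoring rules and band tables

The scale-anchored thresholds are hard-coded defaults:

| Parameter | Rule |
|---|---|
| #1 initial contact | foot-axis angle at strike: > 20° heel (0), 0–20° flat (1), < 0° toe (2) |
| #16 trunk sagittal | within ±5° normal; > 5° backward or 5–15° forward moderate; > 15° forward marked |
| #17 lateral trunk shift | toward stance side: 0–5° normal, < 0° reduced, 5–15° moderate, > 15° marked |
| #8 knee progression | coronal ankle angle within ±25° normal, beyond = internal/external rotation |
| #13 peak hip flexion | 25–45° normal, 45–60° moderate |
| #5 foot rotation | ±20° normal, 20–40° external moderate, > 40° marked; internal bands mirrored |

For #5 the internal-rotation bands mirror the external ones, as the
internal cues in circulation appear label-swapped. All other angle parameters (#3, #7, #9, #10, #11, #12, #14,
#15) have no numeric bands in the open literature — they live in the EVGS
manual — so the package ships documented placeholders and **expects them to be
overridden** via `evgs_config(bands = ...)`. These placeholders were
calibrated once against the synthetic healthy development walks — the
same development-set calibration one would perform with real videos —
and frozen: e.g. the stance/swing dorsiflexion surrogates read ≈ 22°/23°
on normal gait here, so their normal bands are 0–30° and −10–30°, and
the terminal-swing knee surrogate reads 13–19° (video keypoints place
peak knee extension higher than goniometry), giving a normal band up
to 25°. Band tables are lower-inclusive, upper-exclusive, must
partition the line, and are checked for monotonicity: walking outward
from the normal band never decreases the ordinal.

Event-anchored parameters:

* **Heel lift (#2)** — midstance posture first: a foot-axis pitch
  beyond ±`midstance_pitch_deg = 10°` *both* in early stance (25% of
  stance) and at mid-midstance means toe-only ("no heel contact") or
  heel-only ("no forefoot contact") walking. The early-stance check is
  a deliberate deviation from a pure midstance test: an early heel
  lift also has the heel up at mid-midstance, and without the second
  probe it would be misclassified as toe walking. For a flat stance,
  the heel-lift frame is the first ≥ `heel_lift_rise_px = 3` px rise
  above the early-stance plateau (first-quartile median) sustained for
  `heel_lift_sustain = 3` frames, searched over the whole stance so
  early lifts are detectable. Lift between mid-midstance and the
  opposite strike is normal; before, early; after (or never), delayed.
* **Foot clearance (#6)** — evaluated at the opposite leg's
  mid-midstance (the swing foot of interest is passing). "Above" means
  clearing by more than `clearance_tol_px = 3` px, so a toe dragged at
  ground level is not flipped to "above" by pixel noise. High step
  (toe above the stance ankle–knee midpoint) maps to ordinal 1 by
  default (`high_step_ordinal`), as the scale assigns it no ordinal.
* **Aggregation** — the per-leg score is the most frequent per-stride
  ordinal; ties resolve to the worse score so a genuine deviation is
  not averaged away. Unscorable parameters carry a reason and are
  never silently 0; parameters of the other camera view are flagged
  not-applicable, keeping 17 entries per leg always.

## The synthetic generator

`generate_gait()` drives a planar linked-segment walker: feet follow
ground-anchored stance/swing trajectories (heel-pivot loading, toe-pivot
push-off with a sinusoidal heel-rise ramp, constant-velocity swing
decelerating over the final 15% to 1.5× pelvis speed so the
pelvis-relative heel distance peaks exactly at touchdown), the knee is
placed by two-link inverse kinematics from a translating hip root that
vaults vertically at step frequency, and trunk, head and arms ride on
top. The coronal view is a pinhole projection of a walker moving along
the camera axis, with 2° of physiologic trunk sway toward the stance
side — without that sway the lateral-shift rule ("< 0° = reduced")
sits on a knife edge for a perfectly symmetric walker and pixel noise
decides the score. Default conditions: 60 Hz, cadence 100 steps/min
(72-frame stride), 5 strides, 1920×1080 landscape, body scale 0.6 of a
~1700 px adult, stride 288 px; the healthy walk was tuned to normative
kinematics (peak hip flexion ≈ 42°, peak knee flexion ≈ 70°, stance
knee minimum ≈ 8–9°, stance dorsiflexion ≈ 22°) before any scoring
test existed. Gaussian pixel noise and confidence-correlated dropout
(confidence drawn below the 10% gate, so preprocessing is exercised)
are applied last; ground truth — event frames, per-frame joint angles,
intended categories per injected deviation — is recorded pre-noise.
Coronal swing clearance is deliberately modest (12 px at unit scale):
in a frontal projection a large foot lift masks the depth-separation
signal that carries the toe-distance extrema.

What the generator does **not** emulate: soft-tissue and clothing
artifact, camera shake and rolling shutter, perspective in the sagittal
view, keypoint left/right swapping (the documented worst failure mode
of real pose estimation), bystanders and reflections, turning
segments, and pathological coordination patterns beyond the injected
deviations. Passing tests on it therefore demonstrate the correctness
of the rules and detectors under the stated geometry and noise, not
clinical validity on patient video.

## Numerical choices

Cubic gap filling uses `stats::spline` (FMM); zero-phase filtering is
forward–backward `signal::filter` with `signal::butter` coefficients
and odd-reflection padding (`filtfilt`'s default edge handling distorts
segment ends); extremum ties resolve to the earliest frame; inverse
kinematics clamps the hip–ankle distance 0.5 px inside the reachable
interval; degenerate (coincident-endpoint) segments yield missing
angles frame-wise in vector context and abort for scalar calls.

## Validation problem sizes

The test suite and acceptance script use 3-stride walks (~250 frames):
50 seeded walks per noise level for event recovery, 100 seeded walks
across views/directions/noise for scene classification, 100 seeded
walks (4 deviations × 25 seeds) for parameter recovery, and 10⁴ random
keypoint placements (a quarter with exactly vertical segments) for the
angle oracle. These sizes give stable rates while keeping a full run in
tens of seconds.

## Known limitations

* **#15 pelvic rotation**: in a sagittal projection the inter-hip line
  collapses toward a point; its orientation against the vertical axis
  carries essentially no rotation information, and the measured 90°-ish
  angles score "marked" on any walk. The parameter is computed as
  defined, flagged low-confidence, and excluded from the generator's
  controllable set.
* **#4 hindfoot and #8 knee progression** rely on ankle/heel/foot
  keypoints that are the least reliable in real footage; their rules
  are implemented as defined but should be read with the same caution.
* The coronal strike-side attribution (leading-foot depth heuristic)
  assumes a straight approach/recede path.
* Band placeholders are calibrated to this package's angle surrogates,
  not to goniometric conventions; compare like with like when
  overriding them.
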