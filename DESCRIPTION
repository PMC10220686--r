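Package: evgait
Title: Automated Edinburgh Visual Gait Score from 2-D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Edinburgh Visual Gait Score (EVGS) from per-frame
    2-D body keypoints in the OpenPose BODY25 layout. Provides keypoint
    preprocessing (confidence gating, cubic-spline gap filling, zero-phase
    Butterworth smoothing), camera view and walking-direction detection,
    coordinate-based gait event detection and stride segmentation,
    slope-based joint and segment angle computation, rule-based ordinal
    scoring of the 17 EVGS parameters per leg, a synthetic gait generator
    with known ground truth for validation, and evaluation metrics
    (confusion matrices, frame-discrepancy categories, score correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
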