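#' Pipeline configuration
#'
#' Every tunable of the pipeline with its default. Defaults reproduce
#' the method's reference settings (10% confidence gate, 5-frame gap fill,
#' 12 Hz second-order dual-pass filter, 99 px view threshold at 1080 px
#' image height, +/-25 degree knee-progression bands, 0-20 degree flat-foot
#' window); settings the method leaves open (peak-finder parameters,
#' heel-lift detection, clearance tolerance) carry documented defaults.
#'
#' @param ... Named overrides of any default.
#' @return Named list of settings (class `evgs_config`).
#' @export
evgs_config <- function(...) {
  cfg <- list(
    # keypoint preprocessing
    conf_threshold = 0.10,
    conf_gate_inclusive = FALSE,   # "below 10%" read strictly
    max_gap = 5,                   # frames (0.083 s at 60 Hz)
    cutoff_hz = 12,
    filter_order = 2,
    filter_padlen = 30L,
    # view / direction
    view_threshold_px = 99,
    view_ref_height = 1080,
    # event detection
    peak_min_sep_s = 0.4,          # minimum event separation, seconds
    peak_prom_frac = 0.05,         # prominence, fraction of signal range
    # scoring
    flat_foot_max_deg = 20,        # initial contact: flat-foot upper bound
    knee_progression_deg = 25,
    terminal_swing_frac = 0.2,     # final fraction of swing
    heel_lift_rise_px = 3,         # sustained heel rise marking heel lift
    heel_lift_sustain = 3,         # frames the rise must persist
    midstance_pitch_deg = 10,      # |foot-axis angle| beyond which stance is
                                   # toe-only (<0) or heel-only (>0)
    clearance_tol_px = 3,          # margin for "above" comparisons
    high_step_ordinal = 1L,
    bands = default_bands())
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config setting(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- c("evgs_config", "list")
  cfg
}

band_table <- function(lo, hi, ordinal, label) {
  data.frame(lo = lo, hi = hi, ordinal = as.integer(ordinal), label = label,
             stringsAsFactors = FALSE)
}

#' Default score-band tables
#'
#' Ordered numeric bands mapping a measured angle to an ordinal score
#' (0 normal, 1 moderate, 2 marked) and a categorical label. Bands are
#' lower-inclusive, upper-exclusive and partition the real line. The
#' peak-hip-flexion bands (25-45 normal, 45-60 moderate) are the scale's
#' reference anchors; the remaining angle-parameter bands are documented
#' defaults chosen around normative sagittal gait kinematics and are
#' intended to be overridden with locally calibrated values.
#'
#' @return Named list of band data frames, keyed `p3`, `p4`, `p5`, `p7`,
#'   `p9`, `p10`, `p11`, `p12`, `p13`, `p14`, `p15`.
#' @export
default_bands <- function() {
  list(
    # max ankle dorsiflexion in stance (deg from neutral)
    p3 = band_table(c(-Inf, -10, 0, 30, 45), c(-10, 0, 30, 45, Inf),
                    c(2, 1, 0, 1, 2),
                    c("plantarflexed marked", "plantarflexed", "normal",
                      "increased", "increased marked")),
    # hindfoot line vs vertical (valgus positive)
    p4 = band_table(c(-Inf, -15, -5, 5, 15), c(-15, -5, 5, 15, Inf),
                    c(2, 1, 0, 1, 2),
                    c("varus marked", "varus", "normal", "valgus",
                      "valgus marked")),
    # coronal foot rotation (external positive)
    p5 = band_table(c(-Inf, -40, -20, 20, 40), c(-40, -20, 20, 40, Inf),
                    c(2, 1, 0, 1, 2),
                    c("internal marked", "internal moderate", "normal",
                      "external moderate", "external marked")),
    # max ankle dorsiflexion in swing (deg from neutral)
    p7 = band_table(c(-Inf, -25, -10, 30, 40), c(-25, -10, 30, 40, Inf),
                    c(2, 1, 0, 1, 2),
                    c("plantarflexed marked", "plantarflexed", "normal",
                      "increased", "increased marked")),
    # peak knee extension in stance (minimum knee angle, deg)
    p9 = band_table(c(-Inf, -15, 25, 40), c(-15, 25, 40, Inf),
                    c(1, 0, 1, 2),
                    c("hyperextended", "normal", "reduced extension",
                      "fixed flexion")),
    # knee extension in terminal swing (minimum knee angle, deg)
    p10 = band_table(c(-Inf, -15, 25, 40), c(-15, 25, 40, Inf),
                     c(1, 0, 1, 2),
                     c("hyperextended", "normal", "reduced extension",
                       "marked flexion")),
    # peak knee flexion in swing (maximum knee angle, deg)
    p11 = band_table(c(-Inf, 30, 45, 75, 90), c(30, 45, 75, 90, Inf),
                     c(2, 1, 0, 1, 2),
                     c("reduced marked", "reduced", "normal", "increased",
                       "increased marked")),
    # peak hip extension in stance (minimum hip angle, deg)
    p12 = band_table(c(-Inf, 5, 20), c(5, 20, Inf), c(0, 1, 2),
                     c("normal", "reduced extension", "fixed flexion")),
    # peak hip flexion in swing (maximum hip angle, deg); 25-45 / 45-60
    # are the reference anchors
    p13 = band_table(c(-Inf, 10, 25, 45, 60), c(10, 25, 45, 60, Inf),
                     c(2, 1, 0, 1, 2),
                     c("reduced marked", "reduced", "normal", "increased",
                       "increased marked")),
    # max pelvic obliquity in stance (|hip line vs horizontal|, deg)
    p14 = band_table(c(-Inf, 0, 5, 15), c(0, 5, 15, Inf), c(0, 0, 1, 2),
                     c("normal", "normal", "moderate", "marked")),
    # pelvic rotation in midstance (|hip line vs vertical|, deg);
    # low-confidence surrogate, see package vignette
    p15 = band_table(c(-Inf, 0, 5, 10), c(0, 5, 10, Inf), c(0, 0, 1, 2),
                     c("normal", "normal", "moderate", "marked")))
}

#' Map a value through a band table
#'
#' Bands are lower-inclusive, upper-exclusive.
#'
#' @param value Measured value (scalar).
#' @param table A band data frame (`lo`, `hi`, `ordinal`, `label`).
#' @return List with `ordinal` and `label` (`NA` for `NA` input).
#' @export
score_band <- function(value, table) {
  if (is.na(value)) return(list(ordinal = NA_integer_, label = NA_character_))
  row <- which(value >= table$lo & value < table$hi)
  if (length(row) != 1) stop("band table does not partition at value ", value)
  list(ordinal = table$ordinal[row], label = table$label[row])
}
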