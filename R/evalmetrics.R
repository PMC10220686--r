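#' Construct a 2x2 confusion matrix
#'
#' @param tp,fn,fp,tn Non-negative counts (true positive, false negative,
#'   false positive, true negative).
#' @param positive Name of the positive class (bookkeeping only).
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, fn, fp, tn, positive = "positive") {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, positive = positive),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Derived binary-classification metrics
#'
#' Accuracy and F1 are convention-independent. Under the `standard`
#' convention sensitivity is TP/(TP+FN) and precision TP/(TP+FP); the
#' `paper` convention transposes the two off-diagonal roles
#' (sensitivity = TP/(TP+FP), precision = TP/(TP+FN)), a transposed
#' reading found in some reports; having both lets tables of either
#' convention be reproduced exactly. Undefined ratios (zero
#' denominators) are returned as `NA`, never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param convention `"standard"` or `"paper"`.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1` (proportions in `[0, 1]`).
#' @export
binary_metrics <- function(cm, convention = c("standard", "paper")) {
  convention <- match.arg(convention)
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  acc <- (cm$tp + cm$tn) / n
  f1 <- safe_ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  if (convention == "standard") {
    list(accuracy = acc,
         sensitivity = safe_ratio(cm$tp, cm$tp + cm$fn),
         specificity = safe_ratio(cm$tn, cm$tn + cm$fp),
         precision = safe_ratio(cm$tp, cm$tp + cm$fp),
         f1 = f1)
  } else {
    list(accuracy = acc,
         sensitivity = safe_ratio(cm$tp, cm$tp + cm$fp),
         specificity = safe_ratio(cm$tn, cm$tn + cm$fn),
         precision = safe_ratio(cm$tp, cm$tp + cm$fn),
         f1 = f1)
  }
}

discrepancy_category <- function(delta) {
  ifelse(abs(delta) <= 2, "within_2",
         ifelse(abs(delta) <= 5, "within_2_to_5", "beyond_5"))
}

#' Frame discrepancies between predicted and ground-truth events
#'
#' Each predicted event is matched greedily to the nearest unused
#' ground-truth event of the same kind and side; unmatched events on
#' either list count as `beyond_5`. Absolute frame differences fall into
#' three categories (<= 2, 3-5, > 5 frames) and the per-video category is
#' the most frequent one.
#'
#' @param pred,truth Event data frames (`frame`, `side`, `kind`).
#' @return List with `deltas` (per matched event), `categories` (per
#'   event incl. unmatched) and `video_category`.
#' @export
frame_discrepancy <- function(pred, truth) {
  deltas <- numeric(0)
  cats <- character(0)
  keys <- unique(rbind(pred[c("side", "kind")], truth[c("side", "kind")]))
  for (i in seq_len(nrow(keys))) {
    p <- pred$frame[pred$side == keys$side[i] & pred$kind == keys$kind[i]]
    g <- truth$frame[truth$side == keys$side[i] & truth$kind == keys$kind[i]]
    used <- rep(FALSE, length(g))
    for (f in sort(p)) {
      if (!any(!used)) { cats <- c(cats, "beyond_5"); next }
      j <- which(!used)[which.min(abs(g[!used] - f))]
      used[j] <- TRUE
      deltas <- c(deltas, f - g[j])
      cats <- c(cats, discrepancy_category(f - g[j]))
    }
    cats <- c(cats, rep("beyond_5", sum(!used)))
  }
  video <- if (length(cats) == 0) NA_character_
           else names(sort(table(cats), decreasing = TRUE))[1]
  list(deltas = deltas, categories = cats, video_category = video)
}

#' Stride-count agreement category
#'
#' @param n_pred,n_truth Non-negative stride counts.
#' @return `"within_2"`, `"within_2_to_5"` or `"beyond_5"`.
#' @export
stride_count_category <- function(n_pred, n_truth) {
  stopifnot(n_pred >= 0, n_truth >= 0)
  discrepancy_category(n_pred - n_truth)
}

#' Pearson correlation of score vectors with qualitative band
#'
#' Bands: very high (0.9-1.0), high (0.7-0.9), moderate (0.5-0.7), low
#' (0.3-0.5), negligible (0.0-0.3). Negative correlations are reported
#' raw with a warning; the band applies to non-negative r only.
#'
#' @param a,b Equal-length numeric (ordinal) vectors, length >= 3.
#' @return List with `r` and `band` (`NA` band for negative r; error on
#'   zero variance).
#' @export
score_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance in a score vector")
  r <- stats::cor(a, b)
  band <- if (r < 0) {
    warning("negative correlation; qualitative band undefined")
    NA_character_
  } else if (r >= 0.9) "very high"
  else if (r >= 0.7) "high"
  else if (r >= 0.5) "moderate"
  else if (r >= 0.3) "low"
  else "negligible"
  list(r = r, band = band)
}
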