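# FOV-restricted evaluation: confusion counts, Acc/Sp/Sn/PPV, ROC and AUC.
#
# Vessel is the positive class. All quantities are computed over in-FOV
# pixels only (the DRIVE convention; including the dark region outside the
# camera aperture would inflate accuracy and specificity).

#' Confusion counts over the field of view
#'
#' @param pred `H x W` binary predicted mask.
#' @param gold `H x W` binary ground-truth mask (or a [label_image]).
#' @param fov optional `H x W` binary FOV mask; default everything.
#' @return List of class `confusion_counts` with integers `TP`, `TN`, `FP`,
#'   `FN` summing to the number of in-FOV pixels.
#' @export
confusion_counts <- function(pred, gold, fov = NULL) {
  if (inherits(gold, "label_image")) gold <- gold$vessels
  if (is.null(fov)) fov <- matrix(1L, nrow(pred), ncol(pred))
  if (!identical(dim(pred), dim(gold)) || !identical(dim(pred), dim(fov))) {
    stopf("confusion_counts: shape mismatch")
  }
  if (!is_binary_grid(pred) || !is_binary_grid(gold)) {
    stopf("confusion_counts: pred and gold must be binary")
  }
  p <- pred[fov == 1]
  g <- gold[fov == 1]
  structure(list(TP = sum(p == 1 & g == 1), TN = sum(p == 0 & g == 0),
                 FP = sum(p == 1 & g == 0), FN = sum(p == 0 & g == 1)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, specificity `TN/(FP+TN)`, sensitivity
#' `TP/(TP+FN)` and positive predictive value `TP/(TP+FP)`. A zero
#' denominator yields `NaN` with a warning; all-zero counts are an error.
#'
#' @param counts a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return Named list `acc`, `sp`, `sn`, `ppv`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  tot <- tp + tn + fp + fn
  if (tot == 0) stopf("seg_metrics: all confusion counts are zero")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warnf("seg_metrics: %s undefined (zero denominator)", name)
      return(NaN)
    }
    num / den
  }
  list(acc = (tp + tn) / tot,
       sp = ratio(tn, fp + tn, "specificity"),
       sn = ratio(tp, tp + fn, "sensitivity"),
       ppv = ratio(tp, tp + fp, "PPV"))
}

#' ROC curve and AUC over the field of view
#'
#' Sweeps every distinct probability value as a threshold (ties grouped, so
#' the curve steps once per distinct value) and integrates by the
#' trapezoidal rule; the result equals the Mann-Whitney pair-concordance
#' statistic with half credit for ties.
#'
#' @param prob a `probability_map`, or `H x W` matrix of scores.
#' @param gold binary ground truth (matrix or [label_image]).
#' @param fov optional binary FOV mask (taken from `prob` if it is a
#'   `probability_map`).
#' @return List with `roc` (data frame: `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(prob, gold, fov = NULL) {
  if (inherits(prob, "probability_map")) {
    if (is.null(fov)) fov <- prob$fov
    prob <- prob$values
  }
  if (inherits(gold, "label_image")) gold <- gold$vessels
  if (is.null(fov)) fov <- matrix(1L, nrow(prob), ncol(prob))
  if (!identical(dim(prob), dim(gold))) stopf("roc_auc: shape mismatch")
  s <- prob[fov == 1]
  g <- gold[fov == 1]
  np <- sum(g == 1)
  nn <- sum(g == 0)
  if (np == 0 || nn == 0) {
    stopf("roc_auc: need at least one positive and one negative pixel")
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  g <- g[ord]
  last <- cumsum(rle(s)$lengths)  # last index of each distinct score
  tp <- cumsum(g)[last]
  fp <- (seq_along(g) - cumsum(g))[last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Evaluate a segmentation against ground truth
#'
#' Bundles thresholded metrics and ROC/AUC for one image.
#'
#' @param prob a `probability_map`.
#' @param gold binary ground truth.
#' @param threshold binarization threshold.
#' @return List with `counts`, `acc`, `sp`, `sn`, `ppv`, `auc`.
#' @export
evaluate_segmentation <- function(prob, gold, threshold = 0.5) {
  pred <- binarize(prob, threshold)
  counts <- confusion_counts(pred, gold, prob$fov)
  c(seg_metrics(counts), list(auc = roc_auc(prob, gold)$auc,
                              counts = counts))
}
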