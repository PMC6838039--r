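#' Pixel-overlap segmentation scores
#'
#' Standard overlap metrics between a ground-truth nuclei mask `L` and a
#' predicted mask `P`, computed from the pixel confusion counts:
#'
#' * Dice similarity coefficient `DSC = 2TP / (2TP + FP + FN)`
#' * Extra fraction `EF = FP / (TP + FN)` (over-segmentation relative to
#'   the ground-truth area)
#' * Jaccard index `JAC = |L & P| / (L | P)` (intersection over union)
#' * `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`
#'
#' Evaluation is pixel-level throughout; object-matched scores are out of
#' scope.
#'
#' @name seg_eval
NULL

#' Pixel confusion counts between two masks
#'
#' @param label,pred logical masks of identical dimensions (ground truth,
#'   prediction).
#' @return list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(label, pred) {
  if (!is.matrix(label) || !is.matrix(pred) || !all(dim(label) == dim(pred)))
    stop_invalid_input("label and pred must be matrices of identical dimensions")
  l <- label > 0; p <- pred > 0
  list(tp = sum(l & p), fp = sum(!l & p), fn = sum(l & !p), tn = sum(!l & !p))
}

#' Overlap scores for one mask pair
#'
#' When the prediction is empty, precision is reported as 0 with the
#' `empty_prediction` flag set (rather than NaN), so population averages
#' stay defined.
#'
#' @inheritParams confusion_counts
#' @return object of class `he_seg_score`: list with `dsc`, `jac`, `ef`,
#'   `precision`, `recall`, the confusion `counts`, and the
#'   `empty_prediction` flag.
#' @export
seg_score <- function(label, pred) {
  ct <- confusion_counts(label, pred)
  if (ct$tp + ct$fn == 0)
    stop_undefined_metric("empty ground-truth label: overlap scores undefined")
  empty_pred <- ct$tp + ct$fp == 0
  structure(list(
    dsc = 2 * ct$tp / (2 * ct$tp + ct$fp + ct$fn),
    jac = ct$tp / (ct$tp + ct$fp + ct$fn),
    ef = ct$fp / (ct$tp + ct$fn),
    precision = if (empty_pred) 0 else ct$tp / (ct$tp + ct$fp),
    recall = ct$tp / (ct$tp + ct$fn),
    empty_prediction = empty_pred,
    counts = ct), class = "he_seg_score")
}

#' Aggregate overlap scores over a population
#'
#' Sample mean and sample standard deviation per metric; missing values
#' (images whose score was undefined) are excluded and counted. A single
#' defined value yields sd 0 with `n = 1`.
#'
#' @param scores list of `he_seg_score` objects, `NA` entries allowed for
#'   images where scoring failed.
#' @return data.frame with columns metric, n, mean, sd, n_missing.
#' @export
aggregate_scores <- function(scores) {
  if (length(scores) == 0) stop_invalid_input("scores must be non-empty")
  metrics <- c("dsc", "jac", "ef", "precision", "recall")
  tab <- do.call(rbind, lapply(metrics, function(m) {
    x <- vapply(scores, function(s)
      if (inherits(s, "he_seg_score")) s[[m]] else NA_real_, 0)
    ok <- x[!is.na(x)]
    if (length(ok) == 0)
      he_stop(sprintf("metric '%s' undefined for every image", m), "he_undefined_metric")
    data.frame(metric = m, n = length(ok), mean = mean(ok),
               sd = if (length(ok) > 1) stats::sd(ok) else 0,
               n_missing = sum(is.na(x)), stringsAsFactors = FALSE)
  }))
  tab
}
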