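#' Confusion counts for striosome-vs-rest segmentation
#'
#' Counts agreement between a predicted and a reference label map, where
#' the positive class is the striosome label (or `TRUE` for logical
#' masks), within an evaluation region.
#'
#' @param pred,truth Label maps ([label_map()] or logical matrices) of
#'   identical dimensions.
#' @param region Optional logical matrix restricting evaluation (e.g. the
#'   striatal tissue); `NULL` evaluates every pixel. An all-`FALSE` region
#'   yields all-zero counts.
#' @return `list(tp, fp, fn, tn)`; the four counts sum to the number of
#'   evaluated pixels.
#' @export
confusion_counts <- function(pred, truth, region = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth dimensions differ")
  p <- if (is.logical(pred)) pred else pred == 2L
  t <- if (is.logical(truth)) truth else truth == 2L
  if (!is.null(region)) {
    if (!all(dim(region) == dim(pred)))
      stop("evaluation region dimensions differ")
    p <- p[region]; t <- t[region]
  }
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t))
}

#' Segmentation scores from confusion counts
#'
#' `iou = tp/(tp+fp+fn)`, `dice = 2tp/(2tp+fp+fn)`,
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `accuracy = (tp+tn)/total`. Ratios with zero denominator are defined as
#' 1 when both masks are empty (`tp = fp = fn = 0`), else 0.
#'
#' @param counts `list(tp, fp, fn, tn)` from [confusion_counts()].
#' @return List of the five scores.
#' @export
segmentation_score <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  safe <- function(num, den) {
    if (den > 0) num / den else if (tp + fp + fn == 0) 1 else 0
  }
  list(iou = safe(tp, tp + fp + fn),
       dice = safe(2 * tp, 2 * tp + fp + fn),
       precision = safe(tp, tp + fp),
       recall = safe(tp, tp + fn),
       accuracy = (tp + tn) / max(1, tp + fp + fn + tn))
}

#' Score a set of predicted masks in macro and pooled modes
#'
#' Macro mode scores each image separately and averages the scores (the
#' default reporting mode); pooled mode sums the confusion counts over
#' images first, so the identities `dice = 2 iou / (1 + iou)` and
#' `dice = harmonic mean(precision, recall)` hold exactly.
#'
#' @param preds,truths Lists of aligned label maps or logical masks.
#' @param region Optional list of evaluation-region masks.
#' @return Data frame with one row per mode.
#' @export
score_images <- function(preds, truths, region = NULL) {
  stopifnot(length(preds) == length(truths))
  per <- matrix(0, length(preds), 5,
                dimnames = list(NULL, c("iou", "dice", "precision",
                                        "recall", "accuracy")))
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(preds)) {
    cc <- confusion_counts(preds[[i]], truths[[i]],
                           if (is.null(region)) NULL else region[[i]])
    per[i, ] <- unlist(segmentation_score(cc))
    pooled <- pooled + unlist(cc)
  }
  rbind(data.frame(averaging_mode = "macro", t(colMeans(per))),
        data.frame(averaging_mode = "pooled",
                   t(unlist(segmentation_score(as.list(pooled))))))
}

#' Pixel-wise cross-entropy of a probability map
#'
#' Mean negative log-likelihood of the reference striosome mask under the
#' predicted striosome probabilities (clamped away from 0/1 for
#' stability).
#'
#' @param prob Numeric matrix of striosome probabilities in \[0, 1\].
#' @param truth Label map or logical striosome mask.
#' @param eps Clamp for probabilities.
#' @return Mean cross-entropy in nats.
#' @export
cross_entropy <- function(prob, truth, eps = 1e-7) {
  t <- if (is.logical(truth)) truth else truth == 2L
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(ifelse(t, log(p), log(1 - p)))
}
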