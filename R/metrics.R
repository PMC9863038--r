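#' Pixel-wise confusion counts of a predicted mask
#'
#' Compares a predicted highlight mask against a ground-truth mask pixel
#' by pixel: TP (both 1), FP (pred 1, gt 0), FN (pred 0, gt 1), TN (both
#' 0). The four counts always sum to the frame area.
#'
#' @param pred,gt [HighlightMask-class] objects (or 0/1 matrices) of equal
#'   dimensions.
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(pred, gt) {
  p <- .asMaskMatrix(pred); g <- .asMaskMatrix(gt)
  if (!identical(dim(p), dim(g)))
    stop("predicted and ground-truth masks must have equal dimensions")
  list(TP = sum(p == 1L & g == 1L), TN = sum(p == 0L & g == 0L),
       FP = sum(p == 1L & g == 0L), FN = sum(p == 0L & g == 1L))
}

#' Segmentation scores from confusion counts
#'
#' Accuracy, precision, recall, F1, Dice and Jaccard. F1 and Dice are
#' algebraically identical (`2TP / (2TP + FP + FN)`); both are reported.
#' Undefined 0/0 ratios (empty ground truth and prediction) return 0 with
#' a warning -- the conservative convention that never rewards an empty
#' prediction -- while accuracy is always computed normally.
#'
#' @param counts a [confusionCounts()] list.
#' @return named numeric vector with `accuracy`, `precision`, `recall`,
#'   `f1`, `dice`, `jaccard`.
#' @export
detectionScores <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (min(TP, TN, FP, FN) < 0) stop("confusion counts must be >= 0")
  frac <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); returning 0", call. = FALSE)
      0
    } else num / den
  }
  acc <- (TP + TN) / (TP + TN + FP + FN)
  prec <- frac(TP, TP + FP, "precision")
  rec <- frac(TP, TP + FN, "recall")
  f1 <- if (prec + rec == 0) {
    if (TP + FP + FN == 0) warning("f1 undefined (0/0); returning 0",
                                   call. = FALSE)
    0
  } else 2 * prec * rec / (prec + rec)
  dice <- frac(2 * TP, 2 * TP + FP + FN, "dice")
  jac <- frac(TP, TP + FP + FN, "jaccard")
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    dice = dice, jaccard = jac)
}

#' Score a predicted mask against ground truth
#'
#' Convenience wrapper: [confusionCounts()] followed by
#' [detectionScores()].
#'
#' @inheritParams confusionCounts
#' @return named numeric score vector, with the counts attached as
#'   attribute `counts`.
#' @export
scoreDetection <- function(pred, gt) {
  cc <- confusionCounts(pred, gt)
  s <- detectionScores(cc)
  attr(s, "counts") <- cc
  s
}

#' Pool or average scores over a dataset
#'
#' `"pooled"` (default) sums the confusion counts over all image pairs and
#' scores the totals; `"per-image"` scores each pair and averages the six
#' metrics. The two aggregations differ whenever highlight load varies
#' across images.
#'
#' @param preds,gts lists of masks of equal length.
#' @param method `"pooled"` or `"per-image"`.
#' @return named numeric score vector.
#' @export
aggregateScores <- function(preds, gts, method = c("pooled", "per-image")) {
  method <- match.arg(method)
  stopifnot(length(preds) == length(gts), length(preds) > 0L)
  if (method == "pooled") {
    tot <- list(TP = 0, TN = 0, FP = 0, FN = 0)
    for (i in seq_along(preds)) {
      cc <- confusionCounts(preds[[i]], gts[[i]])
      tot <- Map(`+`, tot, cc)
    }
    detectionScores(tot)
  } else {
    rowMeans(vapply(seq_along(preds), function(i)
      detectionScores(confusionCounts(preds[[i]], gts[[i]])),
      numeric(6L)))
  }
}

#' Coefficient of variation of a region's intensity
#'
#' `COV = (sigma / mu) * 100` over the grayscale (BT.601 luma) intensities
#' of the region, with the population standard deviation. A no-reference
#' uniformity measure: the smaller, the more uniform the repaired area.
#' Scale-invariant: multiplying all intensities by a constant leaves it
#' unchanged.
#'
#' @param image an [RgbImage-class].
#' @param region region selector: a logical/0-1 matrix, a
#'   [HighlightMask-class], or a two-column (y, x) index matrix.
#' @return the COV value; `NA` with a warning when the region mean is 0.
#' @export
regionCov <- function(image, region) {
  gray <- .luma(.asPixels(image))
  vals <- if (is.matrix(region) && ncol(region) == 2L &&
              !identical(dim(region), dim(gray))) {
    gray[region]
  } else {
    sel <- .asMaskMatrix(region) == 1L
    gray[sel]
  }
  if (length(vals) == 0L) stop("region is empty")
  mu <- mean(vals)
  if (mu == 0) {
    warning("COV undefined: region mean intensity is 0", call. = FALSE)
    return(NA_real_)
  }
  sigma <- sqrt(mean((vals - mu)^2))
  (sigma / mu) * 100
}
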