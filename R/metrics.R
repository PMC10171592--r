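# Overlap metrics on binarized predictions.

#' Binarize probabilities
#'
#' Thresholds sigmoid outputs at `threshold`; ties (`probs == threshold`)
#' count as foreground.
#'
#' @param probs Array of probabilities in \[0, 1\].
#' @param threshold Scalar in \[0, 1\] (default 0.5).
#' @return Integer 0/1 array of the same shape.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (min(probs) < 0 || max(probs) > 1) {
    stop("probs must lie in [0, 1]", call. = FALSE)
  }
  out <- (probs >= threshold) + 0L
  dim(out) <- dim(probs)
  out
}

#' Pixel-wise confusion counts
#'
#' @param pred Binary predicted mask.
#' @param truth Binary ground-truth mask of the same shape.
#' @return Object of class `confusion_counts`: list with integer `tp`, `fp`,
#'   `fn`, `tn` summing to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || !identical(dim(pred), dim(truth))) {
    stop("pred and truth shapes differ", call. = FALSE)
  }
  p <- pred != 0
  t <- truth != 0
  structure(list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
                 tn = sum(!p & !t)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn,
              x$tn))
  invisible(x)
}

#' Dice coefficient and IoU from confusion counts
#'
#' `dice = 2 TP / (2 TP + FP + FN)` and `iou = TP / (TP + FP + FN)`; the two
#' are linked by `dice = 2 iou / (1 + iou)`.  When prediction and ground
#' truth are both empty (`TP = FP = FN = 0`) both metrics are defined as 1
#' by convention.
#'
#' @param counts A [confusion_counts()] object (or list with `tp`, `fp`,
#'   `fn`).
#' @return Scalar in \[0, 1\].
#' @export
dice_coef <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  2 * counts$tp / den
}

#' @rdname dice_coef
#' @export
iou <- function(counts) {
  den <- counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  counts$tp / den
}
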