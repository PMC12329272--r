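#' Pixelwise confusion counts between two binary masks
#'
#' Tallies agreement between a predicted and a ground-truth binary mask:
#' TP (both 1), FP (predicted 1, truth 0), FN (predicted 0, truth 1) and
#' TN (both 0).
#'
#' @param pred,truth binary arrays of identical shape (values 0/1 or
#'   logical).
#' @return object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @examples
#' confusion_counts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("`pred` and `truth` must have identical shapes", call. = FALSE)
  p <- as.numeric(pred); t <- as.numeric(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("masks must be binary (values 0/1)", call. = FALSE)
  structure(list(TP = sum(p == 1 & t == 1),
                 FP = sum(p == 1 & t == 0),
                 FN = sum(p == 0 & t == 1),
                 TN = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %.0f  FP %.0f  FN %.0f  TN %.0f\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

.as_counts <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion_counts(counts, truth)
  stopifnot(inherits(counts, "confusion_counts"))
  counts
}

#' Intersection over union (Jaccard index)
#'
#' \eqn{IoU = TP / (TP + FN + FP)}: the overlap of predicted and true
#' foreground divided by their union. When both masks are empty
#' (TP = FP = FN = 0) the value is defined as 1 (perfect agreement on
#' absence) and a warning is raised.
#'
#' @param counts a [confusion_counts()] object, or a predicted mask when
#'   `truth` is supplied.
#' @param truth optional ground-truth mask.
#' @return scalar in \[0, 1\].
#' @export
iou <- function(counts, truth = NULL) {
  cc <- .as_counts(counts, truth)
  denom <- cc$TP + cc$FN + cc$FP
  if (denom == 0) {
    warning("both masks empty; IoU defined as 1", call. = FALSE)
    return(1)
  }
  cc$TP / denom
}

#' Dice coefficient
#'
#' \eqn{Dice = 2 TP / ((TP + FN) + (TP + FP))}: twice the overlap divided
#' by the total foreground of both masks. Algebraically
#' \eqn{Dice = 2 IoU / (1 + IoU)}, hence Dice is never below IoU. Defined
#' as 1 (with a warning) when both masks are empty.
#'
#' @inheritParams iou
#' @return scalar in \[0, 1\].
#' @export
dice <- function(counts, truth = NULL) {
  cc <- .as_counts(counts, truth)
  denom <- (cc$TP + cc$FN) + (cc$TP + cc$FP)
  if (denom == 0) {
    warning("both masks empty; Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * cc$TP / denom
}

#' Evaluate a set of predicted masks
#'
#' Computes per-image IoU and Dice plus two dataset aggregates: micro
#' (pool the pixel counts over all images, then apply the metric) and
#' macro (mean of the per-image metrics). Micro weights images by their
#' foreground size; macro weights images equally.
#'
#' @param pairs non-empty list; each element a list with `pred`, `truth`
#'   (binary masks) and optionally `id`.
#' @return object of class `metric_report`: list with `per_image`
#'   (data.frame: id, iou, dice), `micro_iou`, `micro_dice`, `macro_iou`,
#'   `macro_dice`, and the pooled `counts`.
#' @export
evaluate_dataset <- function(pairs) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("`pairs` must be a non-empty list", call. = FALSE)
  n <- length(pairs)
  ids <- character(n); ious <- numeric(n); dices <- numeric(n)
  pooled <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_len(n)) {
    el <- pairs[[i]]
    cc <- confusion_counts(el$pred, el$truth)
    ids[i] <- if (!is.null(el$id)) el$id else as.character(i)
    ious[i] <- iou(cc)
    dices[i] <- dice(cc)
    pooled <- pooled + c(cc$TP, cc$FP, cc$FN, cc$TN)
  }
  pc <- structure(as.list(pooled), class = "confusion_counts")
  structure(list(per_image = data.frame(id = ids, iou = ious, dice = dices,
                                        stringsAsFactors = FALSE),
                 micro_iou = iou(pc), micro_dice = dice(pc),
                 macro_iou = mean(ious), macro_dice = mean(dices),
                 counts = pc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> %d image(s)\n  micro: Dice %.4f, IoU %.4f\n  macro: Dice %.4f, IoU %.4f\n",
    nrow(x$per_image), x$micro_dice, x$micro_iou, x$macro_dice, x$macro_iou))
  invisible(x)
}
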