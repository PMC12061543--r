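#' Multiclass Jaccard (IoU) loss
#'
#' The training loss for the five-class segmentation task:
#' \deqn{L = 1 - \frac{\sum_c \sum_i g_{ic} s_{ic}}
#'                   {\sum_c \sum_i (g_{ic} + s_{ic} - g_{ic} s_{ic})}}
#' where \eqn{s_{ic}} is the predicted probability of class \eqn{c} at
#' pixel \eqn{i} and \eqn{g_{ic}} the one-hot ground truth. By default
#' the sums are pooled over all classes and pixels as a single global
#' ratio (not a mean of per-class Jaccard losses); `reduction =
#' "per_class"` provides the per-class-mean variant. A smoothing epsilon
#' of 1e-7 is added to numerator and denominator.
#'
#' @param s predicted probabilities: matrix or array with the class
#'   dimension first (`C x N` or `C x N x B`), values in `[0, 1]`.
#' @param g one-hot ground-truth indicators with the same shape.
#' @param reduction `"pooled"` (the formula above) or `"per_class"`.
#' @return Scalar loss in `[0, 1]`.
#' @export
iou_loss <- function(s, g, reduction = c("pooled", "per_class")) {
  reduction <- match.arg(reduction)
  if (!all(dim(s) == dim(g)))
    stop("prediction and ground truth shapes differ", call. = FALSE)
  if (min(s) < 0 || max(s) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(g %in% c(0, 1)))
    stop("ground truth must be binary indicators", call. = FALSE)
  eps <- 1e-7
  if (reduction == "pooled") {
    inter <- sum(g * s)
    union <- sum(g + s - g * s)
    return(1 - (inter + eps) / (union + eps))
  }
  C <- dim(s)[1]
  sm <- matrix(s, nrow = C)
  gm <- matrix(g, nrow = C)
  inter_c <- rowSums(gm * sm)
  union_c <- rowSums(gm + sm - gm * sm)
  mean(1 - (inter_c + eps) / (union_c + eps))
}

#' Segmentation quality metrics
#'
#' Per-class intersection-over-union (Jaccard index) and Dice (F1)
#' coefficients averaged over classes, plus pixel accuracy (correct
#' pixels / total pixels). Classes absent from both prediction and truth
#' are skipped from the means.
#'
#' @param pred,truth [label_map()]s (or integer matrices) of equal shape.
#' @param classes class values considered (default all five).
#' @param exclude_background drop class 0 from the IoU/Dice means.
#' @return Named numeric vector `c(mean_iou, mean_dice, accuracy)` with a
#'   `"per_class"` attribute holding the per-class IoU/Dice table.
#' @export
seg_metrics <- function(pred, truth, classes = 0:4,
                        exclude_background = FALSE) {
  p <- unclass(pred); tr <- unclass(truth)
  if (!all(dim(p) == dim(tr))) stop("shapes differ", call. = FALSE)
  if (exclude_background) classes <- setdiff(classes, 0L)
  per <- t(vapply(classes, function(k) {
    pk <- p == k; tk <- tr == k
    inter <- sum(pk & tk); uni <- sum(pk | tk)
    size <- sum(pk) + sum(tk)
    c(iou = if (uni > 0) inter / uni else NA_real_,
      dice = if (size > 0) 2 * inter / size else NA_real_)
  }, c(iou = 0, dice = 0)))
  rownames(per) <- as.character(classes)
  out <- c(mean_iou = mean(per[, "iou"], na.rm = TRUE),
           mean_dice = mean(per[, "dice"], na.rm = TRUE),
           accuracy = mean(p == tr))
  attr(out, "per_class") <- per
  out
}
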