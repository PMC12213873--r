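# ---------------------------------------------------------------------------
# Training objective (weighted BCE + Dice) and segmentation metrics.
# ---------------------------------------------------------------------------

#' Loss weights for the combined objective
#'
#' @param alpha weight of the binary cross-entropy term (default 1).
#' @param beta weight of the Dice term (default 1).
#' @param epsilon Dice smoothing constant (default 1).
#' @return list of validated weights.
#' @export
lossWeights <- function(alpha = 1, beta = 1, epsilon = 1) {
  if (alpha < 0 || beta < 0) stop("lossWeights: weights must be non-negative")
  if (epsilon <= 0) stop("lossWeights: epsilon must be > 0")
  list(alpha = alpha, beta = beta, epsilon = epsilon)
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, differentiable in
#' the predicted probabilities; 0 for a perfect binary match and 1 for
#' disjoint prediction and truth (as `eps -> 0`).
#'
#' @param p probability map in `[0, 1]`.
#' @param g binary ground-truth mask of the same shape.
#' @param epsilon smoothing constant.
#' @return scalar loss.
#' @export
diceLoss <- function(p, g, epsilon = 1) {
  if (!identical(dim0(p), dim0(g)))
    stop("diceLoss: shape mismatch between prediction and mask")
  if (any(p < 0 | p > 1)) stop("diceLoss: probabilities must lie in [0, 1]")
  1 - (2 * sum(p * g) + epsilon) / (sum(p) + sum(g) + epsilon)
}

#' Binary cross-entropy loss
#'
#' Mean of `-[g log p + (1-g) log(1-p)]`. With `from_logits = TRUE` the
#' numerically stable logit form `max(z,0) - z*g + log(1+exp(-|z|))` is
#' used; probabilities supplied directly are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param p probability map (or logits with `from_logits = TRUE`).
#' @param g binary mask of the same shape.
#' @param from_logits interpret `p` as logits.
#' @return scalar loss.
#' @export
bceLoss <- function(p, g, from_logits = FALSE) {
  if (!identical(dim0(p), dim0(g)))
    stop("bceLoss: shape mismatch between prediction and mask")
  if (from_logits) {
    return(mean(pmax(p, 0) - p * g + log1p(exp(-abs(p)))))
  }
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-(g * log(p) + (1 - g) * log(1 - p)))
}

#' Combined segmentation objective
#'
#' `alpha * BCE + beta * Dice`, the training loss of the network; the
#' defaults `alpha = beta = 1` are the weighting found optimal for this
#' architecture.
#'
#' @param p probability map (or logits with `from_logits = TRUE`).
#' @param g binary mask.
#' @param weights a [lossWeights()] list.
#' @param from_logits interpret `p` as logits.
#' @return scalar loss.
#' @export
totalLoss <- function(p, g, weights = lossWeights(), from_logits = FALSE) {
  prob <- if (from_logits) 1 / (1 + exp(-p)) else p
  weights$alpha * bceLoss(p, g, from_logits) +
    weights$beta * diceLoss(prob, g, weights$epsilon)
}

#' Segmentation metrics for one binary mask pair
#'
#' Computes the foreground confusion counts and Dice, precision, recall,
#' foreground IoU and two-class mIoU (mean of foreground and background
#' IoU, the two-class semantic-segmentation convention; the
#' foreground-only IoU is reported alongside). When prediction and truth
#' are both empty the overlap metrics are defined as 1.
#'
#' @param pred binary predicted mask.
#' @param g binary ground-truth mask of the same shape.
#' @return named list: `TP`, `FP`, `FN`, `TN`, `dice`, `precision`,
#'   `recall`, `iou_fg`, `iou_bg`, `miou`.
#' @export
segMetrics <- function(pred, g) {
  if (!identical(dim0(pred), dim0(g)))
    stop("segMetrics: shape mismatch")
  pred <- as.numeric(pred); g <- as.numeric(g)
  if (!all(pred %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("segMetrics: masks must be binary")
  tp <- sum(pred * g)
  fp <- sum(pred * (1 - g))
  fn <- sum((1 - pred) * g)
  tn <- sum((1 - pred) * (1 - g))
  safe <- function(num, den, empty_val) if (den == 0) empty_val else num / den
  dice <- safe(2 * tp, 2 * tp + fp + fn, 1)
  precision <- safe(tp, tp + fp, as.numeric(fn == 0))
  recall <- safe(tp, tp + fn, as.numeric(fp == 0))
  iou_fg <- safe(tp, tp + fp + fn, 1)
  iou_bg <- safe(tn, tn + fp + fn, 1)
  list(TP = tp, FP = fp, FN = fn, TN = tn, dice = dice,
       precision = precision, recall = recall, iou_fg = iou_fg,
       iou_bg = iou_bg, miou = (iou_fg + iou_bg) / 2)
}

# per-image metrics table + aggregate means
metrics_report <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(stem = r$stem, TP = r$TP, FP = r$FP, FN = r$FN, TN = r$TN,
               dice = r$dice, precision = r$precision, recall = r$recall,
               iou_fg = r$iou_fg, miou = r$miou,
               stringsAsFactors = FALSE)))
  agg <- colMeans(df[, c("dice", "precision", "recall", "iou_fg", "miou")])
  new("MetricsReport", perImage = df, aggregate = agg)
}
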