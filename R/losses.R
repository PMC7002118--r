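# Training losses of the extreme-point detector, as pure functions for
# desk-scale verification. No training loop or gradients: these exist so the
# loss surface can be checked against hand-computed values and properties.

#' Modified focal loss for Gaussian-softened keypoint heatmaps
#'
#' Pixel-wise classification loss over a predicted heatmap against
#' Gaussian-softened ground truth. Cells where the ground truth is exactly 1
#' are positives and contribute `(1 - p)^alpha * log(p)`; all other cells
#' contribute `(1 - Y)^beta * p^alpha * log(1 - p)`, so near-keypoint cells
#' (large Y < 1) are down-weighted negatives. The sum is negated and divided
#' by the number of annotated targets.
#'
#' @param pred numeric array of predictions; values are clipped into
#'   `(eps, 1 - eps)` before taking logs.
#' @param gt numeric array of the same shape, values in `[0, 1]`, with
#'   exactly 1 at annotated keypoint cells.
#' @param n_targets number of annotated targets N (>= 1); supplied by the
#'   caller, not inferred from the maps.
#' @param alpha,beta focusing hyper-parameters, defaults 2 and 4.
#' @param eps clipping constant keeping logs finite (default 1e-7).
#' @return a finite non-negative scalar.
#' @examples
#' focal_loss(0.5, 1, n_targets = 1)  # -(0.5)^2 * log(0.5) = 0.1732868
#' @export
focal_loss <- function(pred, gt, n_targets, alpha = 2, beta = 4, eps = 1e-7) {
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  if (length(pred) != length(gt)) {
    abort2("pred and gt must have the same shape", "invalid_input")
  }
  if (!is_scalar_num(n_targets) || n_targets < 1) {
    abort2("n_targets must be >= 1", "invalid_input")
  }
  stopifnot(alpha >= 0, beta >= 0)
  if (any(!is.finite(pred)) || any(!is.finite(gt)) || any(gt < 0) || any(gt > 1)) {
    abort2("pred must be finite and gt in [0, 1]", "invalid_input")
  }
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- gt == 1
  total <- sum((1 - p[pos])^alpha * log(p[pos])) +
    sum((1 - gt[!pos])^beta * p[!pos]^alpha * log(1 - p[!pos]))
  -total / n_targets
}

#' Smooth L1 loss
#'
#' Quadratic near zero, linear beyond: `0.5 x^2` for `|x| < 1`, else
#' `|x| - 0.5`. Continuous with continuous first derivative at `|x| = 1`.
#'
#' @param x numeric vector.
#' @return elementwise loss, same length as `x`.
#' @examples
#' smooth_l1(c(0, 0.5, 2))  # 0, 0.125, 1.5
#' @export
smooth_l1 <- function(x) {
  if (any(!is.finite(x))) abort2("x must be finite", "invalid_input")
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

#' Offset-map regression loss
#'
#' Smooth-L1 loss between predicted sub-cell offsets and the true fractional
#' offsets `x/s - floor(x/s)` lost to down-sampling by factor `s`, summed
#' over both axes and averaged over keypoints.
#'
#' @param predicted numeric `n x 2` matrix of predicted offsets (one row per
#'   keypoint, columns x and y).
#' @param keypoints numeric `n x 2` matrix of true keypoint coordinates in
#'   image pixels.
#' @param s down-sampling factor (positive integer).
#' @param n_targets number of keypoints N; defaults to `nrow(keypoints)` and
#'   must match it.
#' @return mean smooth-L1 offset loss (scalar).
#' @examples
#' offset_loss(matrix(0, 1, 2), matrix(c(13, 15), 1), s = 4)  # 0.3125
#' @export
offset_loss <- function(predicted, keypoints, s, n_targets = nrow(keypoints)) {
  predicted <- matrix(as.numeric(predicted), ncol = 2)
  keypoints <- matrix(as.numeric(keypoints), ncol = 2)
  if (nrow(predicted) != nrow(keypoints)) {
    abort2("one predicted offset pair per keypoint required", "invalid_input")
  }
  if (n_targets != nrow(keypoints) || n_targets < 1) {
    abort2("n_targets must equal the number of keypoints (>= 1)", "invalid_input")
  }
  stopifnot(is_scalar_num(s), s >= 1)
  true_off <- keypoints / s - floor(keypoints / s)
  sum(smooth_l1(predicted - true_off)) / n_targets
}
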