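# COCO-style detection evaluation: IoU, greedy score-ordered matching,
# 101-point interpolated average precision at IoU thresholds 0.50:0.05:0.95,
# averaged per class. Boxes are real rectangles [xmin, ymin, xmax, ymax]
# (no +1 pixel convention).

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b numeric `c(xmin, ymin, xmax, ymax)`, well-ordered per axis.
#' @return IoU in `[0, 1]`; 0 when disjoint or when both boxes have zero
#'   area.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 4L, length(b) == 4L)
  if (a[1] > a[3] || a[2] > a[4] || b[1] > b[3] || b[2] > b[4]) {
    abort2("boxes must satisfy xmin <= xmax and ymin <= ymax", "invalid_input")
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Greedily match detections to ground truth at one IoU threshold
#'
#' Detections are processed by descending score (ties by input order); each
#' is matched one-to-one to the not-yet-matched same-class, same-image
#' ground-truth box of highest IoU, provided that IoU reaches the threshold.
#'
#' @param dets detection data.frame (`image_id`, `class`, `score`, `xmin`,
#'   `ymin`, `xmax`, `ymax`).
#' @param gts ground-truth data.frame (`image_id`, `class`, `xmin`, `ymin`,
#'   `xmax`, `ymax`).
#' @param iou_threshold matching threshold.
#' @return logical vector of TP flags, aligned with `dets` sorted by
#'   descending score; attribute `"order"` holds the sort permutation and
#'   attribute `"matched_gt"` the matched ground-truth row index (NA for
#'   FP).
#' @export
match_detections <- function(dets, gts, iou_threshold) {
  ord <- order(-dets$score)
  tp <- logical(length(ord))
  matched_gt <- rep(NA_integer_, length(ord))
  gt_used <- logical(nrow(gts))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0; best_j <- NA_integer_
    cand <- which(!gt_used &
                    gts$class == dets$class[i] &
                    gts$image_id == dets$image_id[i])
    for (j in cand) {
      v <- box_iou(c(dets$xmin[i], dets$ymin[i], dets$xmax[i], dets$ymax[i]),
                   c(gts$xmin[j], gts$ymin[j], gts$xmax[j], gts$ymax[j]))
      if (v >= iou_threshold && v > best) { best <- v; best_j <- j }
    }
    if (!is.na(best_j)) {
      tp[k] <- TRUE
      gt_used[best_j] <- TRUE
      matched_gt[k] <- best_j
    }
  }
  structure(tp, order = ord, matched_gt = matched_gt)
}

#' 101-point interpolated average precision
#'
#' Builds the precision-recall curve from score-ordered TP/FP flags, takes
#' the monotone precision envelope and samples it at recalls
#' 0, 0.01, ..., 1.00 (the COCO convention), reporting on a 0-100 scale.
#'
#' @param flags logical TP flags in descending-score order.
#' @param n_gt number of ground-truth instances for this class.
#' @return AP in `[0, 100]`; `NA` when `n_gt == 0` and there are no
#'   detections (undefined, excluded from averaging).
#' @export
average_precision <- function(flags, n_gt) {
  stopifnot(n_gt >= 0)
  if (n_gt == 0) {
    return(if (!length(flags)) NA_real_ else 0)
  }
  if (!length(flags)) return(0)
  tp_cum <- cumsum(flags)
  fp_cum <- cumsum(!flags)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # monotone envelope from the right
  envelope <- rev(cummax(rev(precision)))
  rec_grid <- seq(0, 1, by = 0.01)
  # precision at recall r: envelope at the first point with recall >= r
  idx <- findInterval(rec_grid, recall, left.open = TRUE) + 1L
  prec_at <- ifelse(idx <= length(envelope), envelope[idx], 0)
  100 * mean(prec_at)
}

#' Evaluate detections against ground truth
#'
#' Per class and per IoU threshold in 0.50:0.05:0.95, computes the
#' 101-point AP; per-threshold APs are averaged over classes (classes with
#' undefined AP are excluded), and `ap_avg` is the mean over the ten
#' thresholds. Detections of classes absent from the ground truth have no
#' defined AP and are excluded from the class average with a warning (the
#' COCO convention: categories come from the ground truth).
#'
#' @param dets detection data.frame (`image_id`, `class`, `score`, box
#'   columns).
#' @param gts ground-truth data.frame (`image_id`, `class`, box columns).
#' @return an object of class `eval_result`: list with `ap_50`, `ap_75`,
#'   `ap_avg`, `thresholds`, `ap_per_threshold` and the per-class matrix
#'   `ap_by_class`.
#' @export
evaluate_detections <- function(dets, gts) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  classes <- sort(unique(c(as.character(gts$class), as.character(dets$class))))
  extra <- setdiff(unique(as.character(dets$class)), unique(as.character(gts$class)))
  if (length(extra)) {
    warning(sprintf("detections contain classes with no ground truth (FP only): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  ap_mat <- matrix(NA_real_, nrow = length(classes), ncol = length(thresholds),
                   dimnames = list(classes, sprintf("%.2f", thresholds)))
  for (cl in classes) {
    d <- dets[dets$class == cl, , drop = FALSE]
    g <- gts[gts$class == cl, , drop = FALSE]
    if (!nrow(g)) next  # FP-only class: undefined AP, excluded from averaging
    for (ti in seq_along(thresholds)) {
      flags <- match_detections(d, g, thresholds[ti])
      ap_mat[cl, ti] <- average_precision(as.logical(flags), nrow(g))
    }
  }
  per_thr <- apply(ap_mat, 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) NA_real_ else mean(col[ok])
  })
  structure(list(ap_50 = per_thr[["0.50"]], ap_75 = per_thr[["0.75"]],
                 ap_avg = mean(per_thr), thresholds = thresholds,
                 ap_per_threshold = unname(per_thr), ap_by_class = ap_mat),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AP(0.5:0.95) %.2f | AP50 %.2f | AP75 %.2f\n",
              x$ap_avg, x$ap_50, x$ap_75))
  invisible(x)
}
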