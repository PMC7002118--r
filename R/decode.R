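# Heatmap decoding: peak extraction, sub-cell offset refinement, brute-force
# center grouping, optional adjacency-spectrum verification, scoring and
# greedy suppression.

#' Decoder configuration
#'
#' @param peak_threshold minimum heatmap response for a cell to qualify as a
#'   keypoint peak (tau_p, default 0.1).
#' @param center_threshold center-map response a candidate's geometric
#'   center must exceed (tau_c, default 0.1; strict `>` comparison by
#'   default).
#' @param score_threshold minimum combination score kept (default 0.1).
#' @param suppression_iou IoU above which a lower-scored same-class detection
#'   is suppressed (default 0.5).
#' @param max_peaks peaks kept per keypoint type (default 40).
#' @param verify enable adjacency-spectrum verification of candidates
#'   (default FALSE; requires a reference in [detect_cells()]).
#' @param strict_center use strict `>` against `center_threshold` (default
#'   TRUE); FALSE switches to `>=`.
#' @param center_lookup how a candidate center maps to a center-map cell:
#'   `"nearest"` (default) rounds per axis (half-down), `"floor"` truncates,
#'   matching the cell assignment used when rendering ground truth — under
#'   `"floor"` a perfectly decoded center always reads its keypoint's own
#'   cell, so on noise-free maps true combinations score exactly 1.
#' @return an object of class `grouping_config`.
#' @export
grouping_config <- function(peak_threshold = 0.1, center_threshold = 0.1,
                            score_threshold = 0.1, suppression_iou = 0.5,
                            max_peaks = 40L, verify = FALSE,
                            strict_center = TRUE,
                            center_lookup = c("nearest", "floor")) {
  center_lookup <- match.arg(center_lookup)
  for (v in c(peak_threshold, center_threshold, score_threshold, suppression_iou)) {
    if (!is_scalar_num(v) || v < 0 || v > 1) {
      abort2("thresholds must lie in [0, 1]", "invalid_parameter")
    }
  }
  max_peaks <- as.integer(max_peaks)
  if (is.na(max_peaks) || max_peaks < 1L) {
    abort2("max_peaks must be >= 1", "invalid_parameter")
  }
  structure(list(peak_threshold = peak_threshold,
                 center_threshold = center_threshold,
                 score_threshold = score_threshold,
                 suppression_iou = suppression_iou,
                 max_peaks = max_peaks, verify = isTRUE(verify),
                 strict_center = isTRUE(strict_center),
                 center_lookup = center_lookup),
            class = "grouping_config")
}

#' Extract keypoint peaks from a heatmap
#'
#' A grid cell is a peak iff its response is at least `tau_p` and is `>=`
#' every value in its (truncated at edges) `window x window` neighborhood,
#' so plateau cells all qualify. Peaks are returned sorted by response
#' descending, ties broken by row-major scan order, truncated to
#' `max_peaks`.
#'
#' @param heatmap numeric matrix (rows = y, columns = x).
#' @param tau_p peak threshold in `[0, 1]`.
#' @param window odd neighborhood size (default 3).
#' @param max_peaks maximum number of peaks returned (default Inf).
#' @return data.frame with 0-based grid coordinates `x`, `y` and `response`.
#' @export
extract_peaks <- function(heatmap, tau_p = 0.1, window = 3L, max_peaks = Inf) {
  if (!is.matrix(heatmap) || !is.numeric(heatmap) || !length(heatmap)) {
    abort2("heatmap must be a non-empty numeric matrix", "invalid_input")
  }
  if (!all(is.finite(heatmap))) abort2("heatmap must be finite", "invalid_input")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort2("window must be odd", "invalid_input")
  r <- (window - 1L) %/% 2L
  nr <- nrow(heatmap); nc <- ncol(heatmap)
  # neighborhood max via shifted copies, -Inf padding (edge cells compare
  # against their truncated window)
  nb_max <- matrix(-Inf, nr, nc)
  for (dy in -r:r) {
    rows_src <- max(1L, 1L + dy):min(nr, nr + dy)
    rows_dst <- max(1L, 1L - dy):min(nr, nr - dy)
    for (dx in -r:r) {
      cols_src <- max(1L, 1L + dx):min(nc, nc + dx)
      cols_dst <- max(1L, 1L - dx):min(nc, nc - dx)
      nb_max[rows_dst, cols_dst] <-
        pmax(nb_max[rows_dst, cols_dst], heatmap[rows_src, cols_src])
    }
  }
  is_peak <- heatmap >= tau_p & heatmap >= nb_max
  idx <- which(is_peak)
  if (!length(idx)) {
    return(data.frame(x = integer(0), y = integer(0), response = numeric(0)))
  }
  y <- (idx - 1L) %% nr          # 0-based row
  x <- (idx - 1L) %/% nr         # 0-based column
  ord <- order(-heatmap[idx], y, x)
  out <- data.frame(x = x[ord], y = y[ord], response = heatmap[idx][ord])
  utils::head(out, n = if (is.finite(max_peaks)) max_peaks else nrow(out))
}

#' Refine a peak position with the offset map
#'
#' Recovers the sub-cell keypoint position lost to down-sampling:
#' `refined = s * (cell + offset)` per axis. Without an offset map the cell
#' center `s * (cell + 0.5)` is used and a warning is emitted.
#'
#' @param peak numeric `c(x, y)` 0-based grid cell of the peak.
#' @param offset_map list with matrices `dx` and `dy` covering the grid, or
#'   NULL.
#' @param s down-sampling factor.
#' @return numeric `c(x, y)` refined position in image pixels.
#' @examples
#' apply_offset(c(3, 3), list(dx = matrix(0.25, 4, 4), dy = matrix(0.75, 4, 4)), s = 4)
#' @export
apply_offset <- function(peak, offset_map, s) {
  cx <- peak[[1]]; cy <- peak[[2]]
  if (is.null(offset_map)) {
    warning("no offset map: falling back to cell centers", call. = FALSE)
    return(c(s * (cx + 0.5), s * (cy + 0.5)))
  }
  if (cy + 1 > nrow(offset_map$dx) || cx + 1 > ncol(offset_map$dx) ||
      cx < 0 || cy < 0) {
    abort2("offset map does not cover the peak's cell", "invalid_input")
  }
  c(s * (cx + offset_map$dx[cy + 1, cx + 1]),
    s * (cy + offset_map$dy[cy + 1, cx + 1]))
}

refine_peaks <- function(peaks, offset_map, s) {
  if (!nrow(peaks)) {
    peaks$px <- numeric(0); peaks$py <- numeric(0)
    return(peaks)
  }
  if (is.null(offset_map)) {
    warning("no offset map: falling back to cell centers", call. = FALSE)
    peaks$px <- s * (peaks$x + 0.5)
    peaks$py <- s * (peaks$y + 0.5)
  } else {
    ij <- cbind(peaks$y + 1L, peaks$x + 1L)
    peaks$px <- s * (peaks$x + offset_map$dx[ij])
    peaks$py <- s * (peaks$y + offset_map$dy[ij])
  }
  peaks
}

#' Brute-force center grouping of extreme-point peaks
#'
#' Enumerates every (top, left, bottom, right) combination, ordered by a
#' compactness key (ascending sum of pairwise Euclidean distances among the
#' four extremes, ties by score descending), and keeps a combination as a
#' candidate iff (a) it is geometrically valid — `top.y <= bottom.y`,
#' `left.x <= right.x`, each extreme's transverse coordinate falls inside
#' the box (a real cell's leftmost point sits between its top and bottom,
#' and so on), and the induced center lies inside the box — and
#' (b) the center-map response at the center's nearest grid cell exceeds
#' `tau_c`. The candidate score is the mean of the five responses.
#'
#' @param tops,lefts,bottoms,rights peak data.frames as returned by
#'   [extract_peaks()] (after [refine_peaks] they carry pixel positions
#'   `px`, `py`; plain grid peaks are used as-is with `s = 1`).
#' @param center_map numeric matrix of center-point responses on the grid.
#' @param tau_c center threshold.
#' @param s down-sampling factor mapping pixel positions to grid cells
#'   (default 1).
#' @param strict use strict `>` against `tau_c` (default TRUE).
#' @param lookup `"nearest"` (round half-down) or `"floor"` cell lookup for
#'   the center response.
#' @return list of candidates ordered by the compactness key; each has
#'   `extremes` (an [extreme_set] with responses), `score`, `compactness`,
#'   `center_response` and the peak indices `it`, `il`, `ib`, `ir`.
#' @export
center_grouping <- function(tops, lefts, bottoms, rights, center_map,
                            tau_c = 0.1, s = 1, strict = TRUE,
                            lookup = c("nearest", "floor")) {
  lookup <- match.arg(lookup)
  to_cell <- if (lookup == "floor") function(v) as.integer(floor(v)) else nearest_cell
  pos <- function(df) {
    if (!nrow(df)) return(cbind(x = numeric(0), y = numeric(0)))
    if (!is.null(df$px)) cbind(x = df$px, y = df$py) else cbind(x = df$x, y = df$y)
  }
  pt <- pos(tops); pl <- pos(lefts); pb <- pos(bottoms); pr <- pos(rights)
  if (!nrow(pt) || !nrow(pl) || !nrow(pb) || !nrow(pr)) return(list())
  nr <- nrow(center_map); nc <- ncol(center_map)
  grid <- expand.grid(it = seq_len(nrow(pt)), il = seq_len(nrow(pl)),
                      ib = seq_len(nrow(pb)), ir = seq_len(nrow(pr)))
  cands <- vector("list", nrow(grid))
  n_found <- 0L
  for (k in seq_len(nrow(grid))) {
    it <- grid$it[k]; il <- grid$il[k]; ib <- grid$ib[k]; ir <- grid$ir[k]
    t_ <- pt[it, ]; l_ <- pl[il, ]; b_ <- pb[ib, ]; r_ <- pr[ir, ]
    if (t_[2] > b_[2] || l_[1] > r_[1]) next
    # each extreme's transverse coordinate must fall inside the box: the
    # leftmost point of a real cell lies between its top and bottom, etc.
    if (t_[1] < l_[1] || t_[1] > r_[1] || b_[1] < l_[1] || b_[1] > r_[1] ||
        l_[2] < t_[2] || l_[2] > b_[2] || r_[2] < t_[2] || r_[2] > b_[2]) next
    ctr <- c((l_[1] + r_[1]) / 2, (t_[2] + b_[2]) / 2)
    if (ctr[1] < l_[1] || ctr[1] > r_[1] || ctr[2] < t_[2] || ctr[2] > b_[2]) next
    cxg <- to_cell(ctr[1] / s); cyg <- to_cell(ctr[2] / s)
    resp <- if (cxg >= 0 && cyg >= 0 && cxg < nc && cyg < nr) {
      center_map[cyg + 1L, cxg + 1L]
    } else 0
    ok <- if (strict) resp > tau_c else resp >= tau_c
    if (!ok) next
    responses <- c(top = tops$response[it], left = lefts$response[il],
                   bottom = bottoms$response[ib], right = rights$response[ir],
                   center = resp)
    quad <- rbind(t_, l_, b_, r_)
    compact <- sum(stats::dist(quad))
    n_found <- n_found + 1L
    cands[[n_found]] <- list(
      extremes = extreme_set(top = t_, left = l_, bottom = b_, right = r_,
                             center = ctr, responses = responses),
      score = mean(responses), compactness = compact,
      center_response = resp, it = it, il = il, ib = ib, ir = ir)
  }
  cands <- cands[seq_len(n_found)]
  if (!n_found) return(list())
  keys <- vapply(cands, `[[`, numeric(1), "compactness")
  scores <- vapply(cands, `[[`, numeric(1), "score")
  cands[order(keys, -scores)]
}

#' Greedy same-class suppression of overlapping detections
#'
#' Walks detections by descending score (ties stable in input order) and
#' drops any detection whose IoU with an already kept detection of the same
#' class exceeds the threshold.
#'
#' @param detections detection data.frame (needs `class`, `score`, `xmin`,
#'   `ymin`, `xmax`, `ymax`).
#' @param iou_threshold overlap threshold (default 0.5).
#' @return the kept rows, in descending-score order.
#' @export
suppress_detections <- function(detections, iou_threshold = 0.5) {
  if (!nrow(detections)) return(detections)
  ord <- order(-detections$score)
  kept <- integer(0)
  for (i in ord) {
    drop <- FALSE
    for (j in kept) {
      if (detections$class[j] != detections$class[i]) next
      v <- box_iou(unlist(detections[i, c("xmin", "ymin", "xmax", "ymax")]),
                   unlist(detections[j, c("xmin", "ymin", "xmax", "ymax")]))
      if (v > iou_threshold) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  detections[kept, , drop = FALSE]
}

empty_detections <- function() {
  data.frame(class = character(0), score = numeric(0),
             xmin = numeric(0), ymin = numeric(0),
             xmax = numeric(0), ymax = numeric(0),
             r_top = numeric(0), r_left = numeric(0), r_bottom = numeric(0),
             r_right = numeric(0), r_center = numeric(0),
             verified = logical(0), spectrum_distance = numeric(0),
             spec1 = numeric(0), spec2 = numeric(0), spec3 = numeric(0),
             spec4 = numeric(0))
}

#' Decode detections from heatmap stacks
#'
#' Full decoding pipeline, per class: extract peaks from the four
#' extreme-point maps, refine positions with the offset maps, group by
#' brute-force center grouping, then walk the candidates in compactness
#' order. With verification enabled each candidate's adjacency spectrum is
#' checked against the class reference; an accepted candidate consumes its
#' four extreme peaks, so they cannot be combined again, while a rejected
#' candidate leaves its peaks available for later combinations. Finally
#' detections below the score threshold are dropped and greedy suppression
#' is applied.
#'
#' @param bundle a `heatmap_bundle` from [render_heatmaps()] or
#'   [read_heatmap_bundle()].
#' @param config a [grouping_config].
#' @param reference a `spectrum_reference`, or a named list of them (one per
#'   class). Required when `config$verify` is TRUE.
#' @param use_gt decode the clean ground-truth maps instead of the noisy
#'   predicted-style maps (default FALSE).
#' @return detection data.frame, one row per detection: `class`, `score`,
#'   box `xmin`, `ymin`, `xmax`, `ymax` (image pixels), the five responses
#'   `r_top` ... `r_center`, `verified`, and when verification ran the
#'   spectrum (`spec1` ... `spec4`) and `spectrum_distance`.
#' @export
detect_cells <- function(bundle, config = grouping_config(), reference = NULL,
                         use_gt = FALSE) {
  stopifnot(inherits(bundle, "heatmap_bundle"), inherits(config, "grouping_config"))
  if (config$verify && is.null(reference)) {
    abort2("spectrum verification enabled but no reference supplied",
           "configuration_error")
  }
  ref_for <- function(cl) {
    if (is.null(reference)) return(NULL)
    if (inherits(reference, "spectrum_reference")) return(reference)
    reference[[cl]] %||%
      abort2(sprintf("no spectrum reference for class '%s'", cl),
             "configuration_error")
  }
  stacks <- if (use_gt) bundle$gt else bundle$heatmaps
  s <- bundle$s
  out <- list()
  for (cl in bundle$classes) {
    maps <- stacks[[cl]]
    peaks <- lapply(c(top = "top", left = "left", bottom = "bottom", right = "right"),
                    function(tp) {
                      p <- extract_peaks(maps[[tp]], config$peak_threshold,
                                         3L, config$max_peaks)
                      refine_peaks(p, bundle$offsets[[tp]], s)
                    })
    cands <- center_grouping(peaks$top, peaks$left, peaks$bottom, peaks$right,
                             maps$center, config$center_threshold, s = s,
                             strict = config$strict_center,
                             lookup = config$center_lookup)
    if (!length(cands)) next
    ref <- if (config$verify) ref_for(cl) else NULL
    used <- list(top = logical(nrow(peaks$top)), left = logical(nrow(peaks$left)),
                 bottom = logical(nrow(peaks$bottom)), right = logical(nrow(peaks$right)))
    for (cand in cands) {
      if (config$verify &&
          (used$top[cand$it] || used$left[cand$il] ||
           used$bottom[cand$ib] || used$right[cand$ir])) {
        next  # a fully successful target already consumed one of these peaks
      }
      spec <- rep(NA_real_, 4); sdist <- NA_real_; verified <- NA
      if (config$verify) {
        spec <- extreme_spectrum(cand$extremes, normalize = ref$normalized)
        v <- verify_spectrum(spec, ref)
        sdist <- v$distance
        if (!v$accepted) next  # continue combining with these peaks
        verified <- TRUE
        used$top[cand$it] <- used$left[cand$il] <- TRUE
        used$bottom[cand$ib] <- used$right[cand$ir] <- TRUE
      }
      es <- cand$extremes
      out[[length(out) + 1L]] <- data.frame(
        class = cl, score = cand$score,
        xmin = es$left[1], ymin = es$top[2],
        xmax = es$right[1], ymax = es$bottom[2],
        r_top = es$responses[["top"]], r_left = es$responses[["left"]],
        r_bottom = es$responses[["bottom"]], r_right = es$responses[["right"]],
        r_center = es$responses[["center"]],
        verified = verified, spectrum_distance = sdist,
        spec1 = spec[1], spec2 = spec[2], spec3 = spec[3], spec4 = spec[4])
    }
  }
  dets <- if (length(out)) do.call(rbind, out) else empty_detections()
  rownames(dets) <- NULL
  dets <- dets[dets$score >= config$score_threshold, , drop = FALSE]
  suppress_detections(dets, config$suppression_iou)
}
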