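# Independent brute-force / closed-form oracles used across the suite.
# These deliberately re-derive results by different algorithms than the
# package: per-cell scans, exhaustive enumeration, characteristic-polynomial
# roots, dense boundary sampling, and a transcription of the COCO
# evaluator's accumulation scheme.

# ---- peak extraction oracle: literal per-cell neighborhood scan ----------
oracle_peaks <- function(M, tau_p, window = 3L) {
  r <- (window - 1L) %/% 2L
  nr <- nrow(M); nc <- ncol(M)
  out <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- M[i, j]
      if (v < tau_p) next
      nb <- M[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)]
      if (v >= max(nb)) {
        out[[length(out) + 1L]] <- c(x = j - 1L, y = i - 1L, response = v)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(x = integer(0), y = integer(0), response = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(-df$response, df$y, df$x), ]
}

# ---- center grouping oracle: nested-loop enumeration ---------------------
oracle_grouping <- function(tops, lefts, bottoms, rights, center_map, tau_c,
                            s = 1, strict = TRUE, lookup = "nearest") {
  cell_of <- if (lookup == "floor") function(v) floor(v) else function(v) ceiling(v - 0.5)
  res <- list()
  for (it in seq_len(nrow(tops))) for (il in seq_len(nrow(lefts))) {
    for (ib in seq_len(nrow(bottoms))) for (ir in seq_len(nrow(rights))) {
      px <- function(df, i) if (!is.null(df$px)) c(df$px[i], df$py[i]) else c(df$x[i], df$y[i])
      tt <- px(tops, it); ll <- px(lefts, il); bb <- px(bottoms, ib); rr <- px(rights, ir)
      if (tt[2] > bb[2] || ll[1] > rr[1]) next
      if (tt[1] < ll[1] || tt[1] > rr[1] || bb[1] < ll[1] || bb[1] > rr[1]) next
      if (ll[2] < tt[2] || ll[2] > bb[2] || rr[2] < tt[2] || rr[2] > bb[2]) next
      ctr <- c((ll[1] + rr[1]) / 2, (tt[2] + bb[2]) / 2)
      cx <- cell_of(ctr[1] / s); cy <- cell_of(ctr[2] / s)
      resp <- if (cx >= 0 && cy >= 0 && cx < ncol(center_map) && cy < nrow(center_map)) {
        center_map[cy + 1, cx + 1]
      } else 0
      if (if (strict) resp <= tau_c else resp < tau_c) next
      res[[length(res) + 1L]] <- list(
        it = it, il = il, ib = ib, ir = ir,
        score = mean(c(tops$response[it], lefts$response[il],
                       bottoms$response[ib], rights$response[ir], resp)))
    }
  }
  res
}

cand_key <- function(c_) sprintf("%d-%d-%d-%d", c_$it, c_$il, c_$ib, c_$ir)

# ---- spectrum oracle: characteristic polynomial roots --------------------
oracle_spectrum <- function(A) {
  cp <- pracma::charpoly(A)   # monic coefficients, highest degree first
  roots <- polyroot(rev(cp))
  stopifnot(max(abs(Im(roots))) < 1e-7)
  sort(Re(roots), decreasing = TRUE)
}

random_extreme_set <- function() {
  # a plausible extreme-point quadrilateral: distinct points with the
  # top/bottom/left/right roles consistent
  ctr <- runif(2, -50, 50)
  w <- runif(1, 4, 40); h <- runif(1, 4, 40)
  extreme_set(
    top    = ctr + c(runif(1, -w / 2, w / 2), -h),
    bottom = ctr + c(runif(1, -w / 2, w / 2), h),
    left   = ctr + c(-w, runif(1, -h / 2, h / 2)),
    right  = ctr + c(w, runif(1, -h / 2, h / 2)))
}

# ---- dense boundary-sampling oracle for extreme points -------------------
oracle_extremes_dense <- function(spec, n_dense = 4096L) {
  poly <- make_shape(spec, n_dense)
  list(top = poly[which.min(poly[, 2]), ], bottom = poly[which.max(poly[, 2]), ],
       left = poly[which.min(poly[, 1]), ], right = poly[which.max(poly[, 1]), ])
}

random_shape_spec <- function() {
  fam <- sample(c("ellipse", "crescent", "spindle", "pear"), 1)
  size <- switch(fam,
    ellipse = c(a = runif(1, 5, 20), b = runif(1, 3, 15)),
    crescent = {
      R <- runif(1, 6, 15); r <- R * runif(1, 0.7, 0.95)
      c(outer_r = R, inner_r = r, offset = (R - r) + R * runif(1, 0.3, 0.9))
    },
    spindle = {
      L <- runif(1, 15, 35); c(length = L, width = L * runif(1, 0.1, 0.3))
    },
    pear = {
      r1 <- runif(1, 5, 10)
      c(r_big = r1, r_small = r1 * runif(1, 0.4, 0.8), offset = r1 * runif(1, 0.8, 1.4))
    })
  shape_spec(fam, center = runif(2, -20, 20), size = size,
             orientation = runif(1, 0, 2 * pi))
}

# ---- independent point-in-polygon (crossing number, no edge tolerance) ---
oracle_point_in_poly <- function(x, y, poly) {
  n <- nrow(poly); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
      xi <- poly[i, 1] + (y - poly[i, 2]) / (poly[j, 2] - poly[i, 2]) *
        (poly[j, 1] - poly[i, 1])
      if (x < xi) inside <- !inside
    }
    j <- i
  }
  inside
}

# overlap oracle: any dense boundary sample of one polygon inside the other
oracle_polys_overlap <- function(a, b) {
  any(vapply(seq_len(nrow(a)), function(k) oracle_point_in_poly(a[k, 1], a[k, 2], b),
             logical(1))) ||
    any(vapply(seq_len(nrow(b)), function(k) oracle_point_in_poly(b[k, 1], b[k, 2], a),
               logical(1)))
}

# ---- COCO evaluator transcription (evalImgs + accumulate) ----------------
cocoeval_oracle <- function(dets, gts, iou_thresholds = seq(0.5, 0.95, 0.05)) {
  cats <- sort(unique(as.character(gts$class)))
  imgs <- sort(unique(c(dets$image_id, gts$image_id)))
  rec_thrs <- seq(0, 1, 0.01)
  ap_per_thr_cat <- matrix(NA_real_, length(iou_thresholds), length(cats))
  for (ci in seq_along(cats)) {
    cat_ <- cats[ci]
    # per-image matching
    all_scores <- numeric(0)
    all_matches <- vector("list", length(iou_thresholds))
    for (ti in seq_along(iou_thresholds)) all_matches[[ti]] <- logical(0)
    npig <- 0L
    for (im in imgs) {
      d <- dets[dets$class == cat_ & dets$image_id == im, , drop = FALSE]
      g <- gts[gts$class == cat_ & gts$image_id == im, , drop = FALSE]
      npig <- npig + nrow(g)
      if (!nrow(d)) next
      d <- d[order(-d$score), , drop = FALSE]
      ious <- matrix(0, nrow(d), max(1L, nrow(g)))
      if (nrow(g)) {
        for (di in seq_len(nrow(d))) for (gi in seq_len(nrow(g))) {
          ious[di, gi] <- box_iou(
            c(d$xmin[di], d$ymin[di], d$xmax[di], d$ymax[di]),
            c(g$xmin[gi], g$ymin[gi], g$xmax[gi], g$ymax[gi]))
        }
      }
      for (ti in seq_along(iou_thresholds)) {
        t <- iou_thresholds[ti]
        gtm <- rep(FALSE, max(1L, nrow(g)))
        dtm <- rep(FALSE, nrow(d))
        if (nrow(g)) {
          for (di in seq_len(nrow(d))) {
            iou <- min(t, 1 - 1e-10); m <- -1L
            for (gi in seq_len(nrow(g))) {
              if (gtm[gi]) next
              if (ious[di, gi] < iou) next
              iou <- ious[di, gi]; m <- gi
            }
            if (m > 0) { dtm[di] <- TRUE; gtm[m] <- TRUE }
          }
        }
        all_matches[[ti]] <- c(all_matches[[ti]], dtm)
      }
      all_scores <- c(all_scores, d$score)
    }
    if (npig == 0L) next
    ord <- order(-all_scores)
    for (ti in seq_along(iou_thresholds)) {
      tps <- all_matches[[ti]][ord]
      if (!length(tps)) { ap_per_thr_cat[ti, ci] <- 0; next }
      tp <- cumsum(tps); fp <- cumsum(!tps)
      rc <- tp / npig
      pr <- tp / (tp + fp)
      # envelope, backwards
      for (k in rev(seq_along(pr))[-1]) if (pr[k] < pr[k + 1]) pr[k] <- pr[k + 1]
      inds <- findInterval(rec_thrs, rc, left.open = TRUE) + 1L
      q <- ifelse(inds <= length(pr), pr[inds], 0)
      ap_per_thr_cat[ti, ci] <- mean(q)
    }
  }
  per_thr <- apply(ap_per_thr_cat, 1, function(row) {
    ok <- !is.na(row); if (!any(ok)) NA_real_ else mean(row[ok])
  })
  list(ap_per_threshold = 100 * per_thr,
       ap_50 = 100 * per_thr[1], ap_75 = 100 * per_thr[6],
       ap_avg = 100 * mean(per_thr))
}

# random toy detection scenario for evaluator comparisons
random_eval_scenario <- function(seed) {
  set.seed(seed)
  n_img <- sample(1:3, 1)
  classes <- c("a", "b")
  gts <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    n <- sample(2:6, 1)
    x <- runif(n, 0, 80); y <- runif(n, 0, 80)
    w <- runif(n, 8, 25); h <- runif(n, 8, 25)
    data.frame(image_id = im, class = sample(classes, n, replace = TRUE),
               xmin = x, ymin = y, xmax = x + w, ymax = y + h)
  }))
  dets <- do.call(rbind, lapply(seq_len(nrow(gts)), function(k) {
    out <- list()
    if (runif(1) < 0.85) {  # jittered true positive-ish detection
      j <- runif(4, -4, 4)
      out[[1]] <- data.frame(image_id = gts$image_id[k], class = gts$class[k],
                             score = runif(1),
                             xmin = gts$xmin[k] + j[1], ymin = gts$ymin[k] + j[2],
                             xmax = gts$xmax[k] + j[3], ymax = gts$ymax[k] + j[4])
    }
    if (runif(1) < 0.3) {   # random false positive
      x <- runif(1, 0, 90); y <- runif(1, 0, 90)
      out[[length(out) + 1L]] <- data.frame(
        image_id = gts$image_id[k], class = sample(classes, 1), score = runif(1),
        xmin = x, ymin = y, xmax = x + runif(1, 5, 20), ymax = y + runif(1, 5, 20))
    }
    if (length(out)) do.call(rbind, out) else NULL
  }))
  # fix degenerate jitter
  dets$xmax <- pmax(dets$xmax, dets$xmin + 0.1)
  dets$ymax <- pmax(dets$ymax, dets$ymin + 0.1)
  list(dets = dets, gts = gts)
}

# chain fixture helpers shared by decode/acceptance tests
chain_fixture <- function(n_chains = 4L, seed = 1L) {
  scene <- juxtaposed_chain_scene(n_chains = n_chains, seed = seed)
  bundle <- render_heatmaps(scene, render_config(seed = seed))
  ref <- build_reference(lapply(scene$instances, `[[`, "extremes"),
                         class = "ellipse", radius_rule = "max")
  gt <- scene_boxes(scene); gt$image_id <- 1L
  list(scene = scene, bundle = bundle, ref = ref, gt = gt)
}
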