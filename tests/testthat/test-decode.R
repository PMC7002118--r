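# Hand-built bundle helper: direct control over every map.
manual_bundle <- function(maps_by_type, width, height, s = 1L, sigma = 1.2,
                          class = "cell") {
  hs <- ceiling(height / s); ws <- ceiling(width / s)
  zero <- matrix(0, hs, ws)
  heatmaps <- stats::setNames(list(lapply(
    stats::setNames(c("top", "left", "bottom", "right", "center"),
                    c("top", "left", "bottom", "right", "center")),
    function(tp) maps_by_type[[tp]] %||% zero)), class)
  offsets <- lapply(stats::setNames(c("top", "left", "bottom", "right", "center"),
                                    c("top", "left", "bottom", "right", "center")),
                    function(tp) list(dx = zero, dy = zero))
  structure(list(width = width, height = height, s = s, sigma = sigma,
                 noise_sigma = 0, seed = 1L, classes = class,
                 heatmaps = heatmaps, gt = heatmaps, offsets = offsets),
            class = "heatmap_bundle")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

put <- function(M, x, y, v) { M[y + 1, x + 1] <- v; M }

test_that("peak extraction handles empty, single and plateau cases", {
  expect_identical(nrow(extract_peaks(matrix(0, 8, 8), 0.1)), 0L)
  M <- put(matrix(0, 5, 5), 2, 2, 0.9)
  p <- extract_peaks(M, 0.1)
  expect_identical(nrow(p), 1L)
  expect_identical(c(p$x, p$y, p$response), c(2, 2, 0.9))
  # adjacent equal maxima both qualify under >=; truncation is row-major
  M2 <- put(put(matrix(0, 5, 5), 2, 2, 0.8), 3, 2, 0.8)
  p2 <- extract_peaks(M2, 0.1)
  expect_identical(nrow(p2), 2L)
  expect_identical(p2$x, c(2L, 3L))
  p2t <- extract_peaks(M2, 0.1, max_peaks = 1)
  expect_identical(c(p2t$x, p2t$y), c(2L, 2L))  # scan-order tie break
  expect_error(extract_peaks(matrix(numeric(0), 0, 0), 0.1), class = "invalid_input")
})

test_that("peak extraction equals the per-cell scan oracle on random maps", {
  set.seed(20)
  for (k in 1:200) {
    nr <- sample(c(16L, 64L), 1, prob = c(0.7, 0.3))
    M <- matrix(round(runif(nr * nr), 2), nr)  # rounding forces plateaus
    tau <- runif(1, 0, 0.8)
    got <- extract_peaks(M, tau)
    want <- oracle_peaks(M, tau)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("offset refinement recovers exact sub-cell positions", {
  om <- list(dx = matrix(0.25, 4, 4), dy = matrix(0.75, 4, 4))
  expect_equal(apply_offset(c(3, 3), om, s = 4), c(13, 15))
  om0 <- list(dx = matrix(0, 4, 4), dy = matrix(0, 4, 4))
  expect_equal(apply_offset(c(2, 1), om0, s = 1), c(2, 1))
  expect_warning(v <- apply_offset(c(3, 3), NULL, s = 4), "offset")
  expect_equal(v, c(14, 14))
  expect_error(apply_offset(c(9, 9), om, s = 4), class = "invalid_input")
  # simulator round trip: keypoint at x = 13 decodes to exactly 13
  poly <- make_shape(shape_spec("ellipse", center = c(13, 15), size = c(a = 2, b = 2)), 32L)
  sc <- structure(list(width = 32L, height = 32L, classes = "ellipse", seed = 1L,
                       instances = list(list(spec = NULL, polygon = poly,
                                             extremes = extreme_set(top = c(13, 15), left = c(13, 15),
                                                                    bottom = c(13, 15), right = c(13, 15)),
                                             class = "ellipse"))),
                  class = "cell_scene")
  b <- render_heatmaps(sc, render_config(s = 4L))
  pk <- extract_peaks(b$heatmaps$ellipse$top, 0.5)
  refined <- apply_offset(c(pk$x[1], pk$y[1]), b$offsets$top, 4)
  expect_identical(refined, c(13, 15))
})

test_that("center grouping matches the exhaustive oracle with <= 6 peaks/type", {
  set.seed(21)
  for (k in 1:60) {
    n <- function() sample(0:6, 1)
    mk <- function(m) {
      if (m == 0) return(data.frame(x = integer(0), y = integer(0), response = numeric(0)))
      data.frame(x = sample(0:23, m, replace = TRUE), y = sample(0:23, m, replace = TRUE),
                 response = round(runif(m, 0.2, 1), 3))
    }
    tops <- mk(n()); lefts <- mk(n()); bottoms <- mk(n()); rights <- mk(n())
    cmap <- matrix(round(runif(24 * 24), 2), 24)
    tau <- runif(1, 0, 0.6)
    got <- center_grouping(tops, lefts, bottoms, rights, cmap, tau)
    want <- oracle_grouping(tops, lefts, bottoms, rights, cmap, tau)
    expect_identical(length(got), length(want))
    gk <- vapply(got, function(c_) sprintf("%d-%d-%d-%d", c_$it, c_$il, c_$ib, c_$ir),
                 character(1))
    wk <- vapply(want, cand_key, character(1))
    expect_setequal(gk, wk)
    if (length(got)) {
      gs <- stats::setNames(vapply(got, `[[`, numeric(1), "score"), gk)
      ws <- stats::setNames(vapply(want, `[[`, numeric(1), "score"), wk)
      expect_equal(gs[sort(gk)], ws[sort(gk)], tolerance = 1e-12)
      # ordering: compactness ascending
      keys <- vapply(got, `[[`, numeric(1), "compactness")
      expect_false(is.unsorted(keys))
    }
  }
})

test_that("grouping threshold blocks low center responses", {
  tops <- data.frame(x = 4, y = 0, response = 1)
  lefts <- data.frame(x = 0, y = 4, response = 1)
  bottoms <- data.frame(x = 4, y = 8, response = 1)
  rights <- data.frame(x = 8, y = 4, response = 1)
  cmap <- put(matrix(0, 9, 9), 4, 4, 0.9)
  got <- center_grouping(tops, lefts, bottoms, rights, cmap, 0.1)
  expect_length(got, 1)
  expect_equal(got[[1]]$score, (1 + 1 + 1 + 1 + 0.9) / 5)
  cmap_low <- put(matrix(0, 9, 9), 4, 4, 0.05)
  expect_length(center_grouping(tops, lefts, bottoms, rights, cmap_low, 0.1), 0)
  # any empty peak list: no candidates
  none <- data.frame(x = integer(0), y = integer(0), response = numeric(0))
  expect_length(center_grouping(none, lefts, bottoms, rights, cmap, 0.1), 0)
})

test_that("greedy suppression keeps the expected chain members", {
  d <- data.frame(class = "a", score = c(0.9, 0.8, 0.7),
                  xmin = 0, ymin = c(0, 3, 6), xmax = 10, ymax = c(10, 13, 16))
  kept <- suppress_detections(d, 0.5)
  expect_equal(kept$score, c(0.9, 0.7))  # B suppressed by A; C survives A
  # identical boxes: only the higher score remains
  d2 <- data.frame(class = "a", score = c(0.9, 0.8),
                   xmin = 0, ymin = 0, xmax = 5, ymax = 5)
  expect_equal(suppress_detections(d2, 0.5)$score, 0.9)
  # disjoint boxes survive
  d3 <- data.frame(class = "a", score = c(0.9, 0.8),
                   xmin = c(0, 20), ymin = 0, xmax = c(5, 25), ymax = 5)
  expect_identical(nrow(suppress_detections(d3, 0.5)), 2L)
})

# Juxtaposed-pair fixture with a spurious middle candidate: peaks at the
# extremes of two circles A (center (10,10)) and B (center (24,22)), radius
# 6, center map lit only at the two true centers and the wide combination's
# midpoint M = (17, 16).
pair_bundle <- function(mid_response = 0.9) {
  z <- matrix(0, 32, 36)
  tmap <- put(put(z, 10, 4, 1), 24, 16, 1)
  lmap <- put(put(z, 4, 10, 1), 18, 22, 1)
  bmap <- put(put(z, 10, 16, 1), 24, 28, 1)
  rmap <- put(put(z, 16, 10, 1), 30, 22, 1)
  cmap <- put(put(put(z, 10, 10, 1), 24, 22, 1), 17, 16, mid_response)
  manual_bundle(list(top = tmap, left = lmap, bottom = bmap, right = rmap,
                     center = cmap), width = 36, height = 32, s = 1L)
}

pair_reference <- function() {
  mk <- function(cx, cy) extreme_set(top = c(cx, cy - 6), left = c(cx - 6, cy),
                                     bottom = c(cx, cy + 6), right = c(cx + 6, cy))
  build_reference(list(mk(10, 10), mk(24, 22)), class = "cell", radius_rule = "max")
}

test_that("cross-pair grouping yields a spurious candidate that verification rejects", {
  b <- pair_bundle()
  off <- detect_cells(b, grouping_config())
  expect_identical(nrow(off), 3L)  # two true cells + the wide middle box
  expect_true(any(off$xmax - off$xmin > 20))
  on <- detect_cells(b, grouping_config(verify = TRUE), reference = pair_reference())
  expect_identical(nrow(on), 2L)
  expect_true(all(on$xmax - on$xmin == 12))
  expect_true(all(on$verified))
  expect_true(all(is.finite(on$spec1)))
  # without the midpoint response the spurious candidate never forms
  b2 <- pair_bundle(mid_response = 0.05)
  expect_identical(nrow(detect_cells(b2, grouping_config())), 2L)
})

test_that("verification without a reference is a configuration error", {
  expect_error(detect_cells(pair_bundle(), grouping_config(verify = TRUE)),
               class = "configuration_error")
})

test_that("empty heatmaps yield an empty detection frame", {
  b <- manual_bundle(list(), width = 16, height = 16)
  d <- detect_cells(b, grouping_config())
  expect_identical(nrow(d), 0L)
  expect_true(all(c("class", "score", "xmin", "verified") %in% names(d)))
})

test_that("clean single-cell scenes decode to the exact ground-truth box", {
  for (seed in 1:5) {
    sc <- sample_scene(width = 96, height = 96, count_range = c(1, 1), seed = seed)
    b <- render_heatmaps(sc, render_config(seed = seed))
    d <- detect_cells(b, grouping_config())
    expect_identical(nrow(d), 1L)
    gt <- extreme_box(sc$instances[[1]]$extremes)
    expect_lt(max(abs(c(d$xmin, d$ymin, d$xmax, d$ymax) - gt)), 1)
  }
})

test_that("every detection's score is the mean of its five responses", {
  fx <- chain_fixture(n_chains = 3, seed = 4)
  d <- detect_cells(fx$bundle, grouping_config())
  expect_gt(nrow(d), 0)
  resp_mean <- unname(rowMeans(d[, c("r_top", "r_left", "r_bottom", "r_right", "r_center")]))
  expect_equal(d$score, resp_mean, tolerance = 1e-12)
})

test_that("verification-on detections are a subset of verification-off ones", {
  fx <- chain_fixture(n_chains = 4, seed = 6)
  off <- detect_cells(fx$bundle, grouping_config())
  on <- detect_cells(fx$bundle, grouping_config(verify = TRUE), reference = fx$ref)
  key <- function(d) sprintf("%.6f-%.6f-%.6f-%.6f", d$xmin, d$ymin, d$xmax, d$ymax)
  expect_true(all(key(on) %in% key(off)))
  expect_lt(nrow(on), nrow(off))
  # on a fixture without spurious candidates the two sets are identical
  sc <- sample_scene(width = 128, height = 128, count_range = c(3, 4),
                     overlap_fraction = 0, seed = 9, min_spacing = 28)
  b <- render_heatmaps(sc, render_config(seed = 9))
  ref <- build_reference(lapply(sc$instances, `[[`, "extremes"),
                         radius_rule = "max")
  refs <- stats::setNames(rep(list(ref), length(b$classes)), b$classes)
  cfg_off <- grouping_config(center_threshold = 0.9, center_lookup = "floor")
  cfg_on <- grouping_config(center_threshold = 0.9, center_lookup = "floor",
                            verify = TRUE)
  o1 <- detect_cells(b, cfg_off)
  o2 <- detect_cells(b, cfg_on, reference = refs)
  expect_setequal(key(o1), key(o2))
})
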