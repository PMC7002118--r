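# Synthetic microscopy scenes: ground-truth layouts of parameterized cell
# shapes with extreme-point annotations. These stand in for annotated slides,
# so every decoder stage is testable without images or trained weights.

# Per-family size samplers (pixels). Scales approximate small crops from
# 100x oil-immersion fields: nuclei ~20 px across, trypanosomes elongated,
# babesia small and pear shaped.
sample_shape_spec <- function(family, center = c(0, 0)) {
  size <- switch(family,
    ellipse = {
      a <- runif(1, 8, 14)
      c(a = a, b = a * runif(1, 0.7, 1.0))
    },
    crescent = {
      R <- runif(1, 8, 12)
      r <- R * runif(1, 0.75, 0.95)
      c(outer_r = R, inner_r = r, offset = (R - r) + R * runif(1, 0.4, 0.8))
    },
    spindle = {
      L <- runif(1, 20, 30)
      c(length = L, width = L * runif(1, 0.12, 0.2))
    },
    pear = {
      r1 <- runif(1, 6, 9)
      c(r_big = r1, r_small = r1 * runif(1, 0.5, 0.7),
        offset = r1 * runif(1, 1.0, 1.3))
    }
  )
  shape_spec(family, center = center, size = size,
             orientation = runif(1, 0, 2 * pi))
}

#' Sample a synthetic cell scene
#'
#' Places cell shapes in an image of the given size. Microscopy fields are
#' globally sparse but locally dense: a requested fraction of instances is
#' placed as touching/overlapping pairs (partner center closer than the sum
#' of the two nominal radii), the rest are placed without contact by
#' rejection sampling. Instances are sorted by center y then x, so a scene
#' is a deterministic function of its seed.
#'
#' @param width,height scene size in pixels.
#' @param classes character vector of shape families to draw from
#'   (uniform mix).
#' @param count_range integer `c(min, max)` number of instances.
#' @param overlap_fraction fraction of instances placed as overlapping
#'   pairs, in `[0, 1]`.
#' @param seed integer random seed.
#' @param n_vertices polygon resolution per instance.
#' @param max_retries placement attempts per instance before giving up.
#' @param min_spacing extra clearance in pixels required between the nominal
#'   radii of non-paired instances. 0 (default) only forbids polygon
#'   intersection; a large value (e.g. 28 with the default rendering sigma)
#'   yields isolated cells whose cross-combinations receive no center-map
#'   support.
#' @return an object of class `cell_scene`: list with `width`, `height`,
#'   `classes`, `seed` and `instances`, each instance a list with `spec`
#'   ([shape_spec]), `polygon`, `extremes` ([extreme_set]) and `class`.
#' @examples
#' sc <- sample_scene(width = 128, height = 128, classes = "ellipse",
#'                    count_range = c(3, 5), overlap_fraction = 0, seed = 1)
#' length(sc$instances)
#' @export
sample_scene <- function(width = 256L, height = 256L,
                         classes = SHAPE_FAMILIES,
                         count_range = c(6L, 12L),
                         overlap_fraction = 0.3,
                         seed = 1L,
                         n_vertices = 64L,
                         max_retries = 200L,
                         min_spacing = 0) {
  stopifnot(width >= 1, height >= 1, length(count_range) == 2L,
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (any(count_range < 0)) abort2("counts must be >= 0", "invalid_parameter")
  classes <- match.arg(classes, SHAPE_FAMILIES, several.ok = TRUE)
  with_seed(seed, {
    n <- if (count_range[1] == count_range[2]) count_range[1] else
      sample(count_range[1]:count_range[2], 1L)
    n_pairs <- floor(round(overlap_fraction * n) / 2)
    placed <- list()   # each: list(spec, polygon, extremes, class, radius)

    margin <- 2  # keep keypoints strictly inside the image
    new_instance <- function(center_sampler, allow_touch_idx = integer(0),
                             require_touch = FALSE) {
      for (attempt in seq_len(max_retries)) {
        fam <- if (length(classes) == 1L) classes else sample(classes, 1L)
        spec0 <- sample_shape_spec(fam)
        poly0 <- make_shape(spec0, n_vertices)
        rad <- max(sqrt(rowSums(sweep(poly0, 2, spec0$center)^2)))
        ctr <- center_sampler(rad)
        if (is.null(ctr)) next
        spec <- shape_spec(fam, center = ctr, size = spec0$size,
                           orientation = spec0$orientation)
        poly <- sweep(poly0, 2, spec0$center) |> sweep(2, ctr, `+`)
        if (min(poly[, 1]) < margin || min(poly[, 2]) < margin ||
            max(poly[, 1]) > width - 1 - margin ||
            max(poly[, 2]) > height - 1 - margin) next
        clash <- FALSE
        for (k in seq_along(placed)) {
          if (k %in% allow_touch_idx) next
          other <- placed[[k]]
          dc <- sqrt(sum((ctr - other$spec$center)^2))
          if (dc <= rad + other$radius + min_spacing &&
              (min_spacing > 0 || polygons_intersect(poly, other$polygon))) {
            clash <- TRUE; break
          }
        }
        if (clash) next
        if (require_touch &&
            !polygons_intersect(poly, placed[[allow_touch_idx[1]]]$polygon)) next
        return(list(spec = spec, polygon = poly,
                    extremes = extreme_points(poly), class = fam,
                    radius = rad))
      }
      NULL
    }

    uniform_center <- function(rad) {
      lo <- rad + margin
      if (lo >= width - 1 - rad - margin || lo >= height - 1 - rad - margin) return(NULL)
      c(runif(1, lo, width - 1 - rad - margin),
        runif(1, lo, height - 1 - rad - margin))
    }

    n_placed_in_pairs <- 0L
    for (p in seq_len(n_pairs)) {
      anchor <- new_instance(uniform_center)
      if (is.null(anchor)) abort2("scene too small to place requested instances",
                                  "placement_error")
      placed[[length(placed) + 1L]] <- anchor
      anchor_idx <- length(placed)
      partner <- new_instance(function(rad) {
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 0.4, 0.9) * (rad + anchor$radius)
        anchor$spec$center + d * c(cos(ang), sin(ang))
      }, allow_touch_idx = anchor_idx, require_touch = TRUE)
      if (is.null(partner)) abort2("scene too small to place requested instances",
                                   "placement_error")
      placed[[length(placed) + 1L]] <- partner
      n_placed_in_pairs <- n_placed_in_pairs + 2L
    }
    for (i in seq_len(n - n_placed_in_pairs)) {
      inst <- new_instance(uniform_center)
      if (is.null(inst)) abort2("scene too small to place requested instances",
                                "placement_error")
      placed[[length(placed) + 1L]] <- inst
    }

    if (length(placed)) {
      ctr_y <- vapply(placed, function(p) p$extremes$center[2], numeric(1))
      ctr_x <- vapply(placed, function(p) p$extremes$center[1], numeric(1))
      placed <- placed[order(ctr_y, ctr_x)]
    }
    structure(list(width = as.integer(width), height = as.integer(height),
                   classes = classes, seed = as.integer(seed),
                   instances = lapply(placed, function(p) p[c("spec", "polygon",
                                                              "extremes", "class")])),
              class = "cell_scene")
  })
}

#' @export
print.cell_scene <- function(x, ...) {
  cat(sprintf("<cell_scene> %d x %d px, %d instances (%s), seed %d\n",
              x$width, x$height, length(x$instances),
              paste(x$classes, collapse = ", "), x$seed))
  invisible(x)
}

#' Ground-truth boxes of a scene as a data frame
#'
#' @param scene a `cell_scene`.
#' @param image_id image identifier attached to every row.
#' @return data.frame with columns `image_id`, `class`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (extreme boxes, pixels).
#' @export
scene_boxes <- function(scene, image_id = 1L) {
  stopifnot(inherits(scene, "cell_scene"))
  if (!length(scene$instances)) {
    return(data.frame(image_id = integer(0), class = character(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0)))
  }
  boxes <- t(vapply(scene$instances, function(i) extreme_box(i$extremes), numeric(4)))
  data.frame(image_id = image_id,
             class = vapply(scene$instances, `[[`, character(1), "class"),
             xmin = boxes[, 1], ymin = boxes[, 2],
             xmax = boxes[, 3], ymax = boxes[, 4])
}

#' Build a locally dense scene of juxtaposed cell chains
#'
#' Constructs the failure mode that motivates spectrum verification: short
#' diagonal chains of three round cells (A, C, B with C midway between A and
#' B). Brute-force center grouping can pair A's top/left extremes with B's
#' bottom/right extremes; the geometric center of that cross-cell combination
#' falls exactly on C's center, so the center map endorses it and the wide
#' spurious candidate scores at least as high as the true cells. Spectrum
#' verification rejects it because its 4-cycle adjacency spectrum is far
#' (roughly 2x in scale) from the reference spectra of single cells.
#'
#' Chain geometry is aligned to a down-sampling factor of 4: A and B centers
#' sit 0.65 of a cell past a grid-cell boundary in x, so their decoded center
#' response is the Gaussian one-cell tail rather than 1.0, while C's center
#' (and hence the spurious candidate's center) hits its own cell exactly.
#'
#' @param n_chains number of three-cell chains.
#' @param seed integer seed (10% cell-size jitter across chains).
#' @param width,height scene size in pixels.
#' @return a `cell_scene` of class `"ellipse"` instances in chains of three.
#' @export
juxtaposed_chain_scene <- function(n_chains = 4L, seed = 1L,
                                   width = 256L, height = 256L) {
  stopifnot(n_chains >= 1)
  with_seed(seed, {
    pitch <- 80  # layout pitch per chain, multiple of s = 4
    # chain footprint: x in [margin - r0, margin + 28 + r0], r0 <= 8.8
    per_row <- max(1L, (width - 56L) %/% pitch + 1L)
    n_rows <- max(1L, (height - 50L) %/% pitch + 1L)
    if (n_chains > per_row * n_rows) {
      abort2("scene too small for requested chains", "placement_error")
    }
    instances <- list()
    for (g in seq_len(n_chains)) {
      r0 <- 8 * runif(1, 0.9, 1.1)      # nominal circle radius, 10% jitter
      gx <- (g - 1L) %% per_row
      gy <- (g - 1L) %/% per_row
      ax <- 12 + gx * pitch + 2.6       # x fraction 2.6 mod 4
      ay <- 12 + gy * pitch + 0.4       # y fraction 0.4 mod 4
      for (ctr in list(c(ax, ay), c(ax + 14, ay + 12), c(ax + 28, ay + 24))) {
        spec <- shape_spec("ellipse", center = ctr, size = c(a = r0, b = r0))
        poly <- make_shape(spec, 64L)
        instances[[length(instances) + 1L]] <-
          list(spec = spec, polygon = poly, extremes = extreme_points(poly),
               class = "ellipse")
      }
    }
    ctr_y <- vapply(instances, function(i) i$extremes$center[2], numeric(1))
    ctr_x <- vapply(instances, function(i) i$extremes$center[1], numeric(1))
    structure(list(width = as.integer(width), height = as.integer(height),
                   classes = "ellipse", seed = as.integer(seed),
                   instances = instances[order(ctr_y, ctr_x)]),
              class = "cell_scene")
  })
}
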