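# Render the keypoint heatmaps and offset maps a trained keypoint network
# would output for a scene: per class, four extreme-point maps and one center
# map on a grid down-sampled by factor s, Gaussian-softened ground truth with
# exact 1.0 at each keypoint's own grid cell, plus sub-cell offsets.

KEYPOINT_TYPES <- c("top", "left", "bottom", "right", "center")

#' Rendering configuration
#'
#' @param sigma Gaussian softening radius in grid cells (> 0). Ground truth
#'   around each keypoint decays as `exp(-d^2 / (2 sigma^2))` with `d` the
#'   grid-cell distance to the keypoint's cell.
#' @param s integer down-sampling factor; the heatmap grid is
#'   `ceiling(H/s) x ceiling(W/s)`.
#' @param noise_sigma standard deviation of additive Gaussian noise applied
#'   to the predicted-style maps (then clipped to `[0, 1]`); 0 for noise-free.
#' @param seed integer seed for the noise.
#' @param salt_pepper fraction of cells replaced by 0 or 1 impulse noise
#'   (optional second noise model, default 0 = off).
#' @return an object of class `render_config`.
#' @export
render_config <- function(sigma = 1.2, s = 4L, noise_sigma = 0, seed = 1L,
                          salt_pepper = 0) {
  if (!is_scalar_num(sigma) || sigma <= 0) abort2("sigma must be > 0", "invalid_parameter")
  s <- as.integer(s)
  if (is.na(s) || s < 1L) abort2("s must be a positive integer", "invalid_parameter")
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0) {
    abort2("noise_sigma must be >= 0", "invalid_parameter")
  }
  stopifnot(salt_pepper >= 0, salt_pepper <= 1)
  structure(list(sigma = sigma, s = s, noise_sigma = noise_sigma,
                 seed = as.integer(seed), salt_pepper = salt_pepper),
            class = "render_config")
}

# Gaussian bump (integer grid-cell distances) maxed into map M at cell
# (cx, cy), 0-based.
add_bump <- function(M, cx, cy, sigma) {
  nr <- nrow(M); nc <- ncol(M)
  dy2 <- (seq_len(nr) - 1L - cy)^2
  dx2 <- (seq_len(nc) - 1L - cx)^2
  g <- exp(-outer(dy2, dx2, `+`) / (2 * sigma^2))
  pmax(M, g)
}

#' Render heatmap and offset stacks for a scene
#'
#' Every keypoint (four extremes + center per instance) contributes an
#' unnormalized Gaussian centered on its grid cell, combined across instances
#' by elementwise max so the map stays in `[0, 1]` with an exact 1.0 at every
#' annotated keypoint cell. Class-agnostic offset maps store, at each
#' keypoint's coarse cell, the true sub-cell fractional position
#' `x/s - floor(x/s)` per axis. Predicted-style maps add seeded Gaussian
#' noise and clip to `[0, 1]`; the clean ground-truth maps are returned
#' alongside.
#'
#' @param scene a `cell_scene`.
#' @param config a [render_config].
#' @return an object of class `heatmap_bundle`: list with `width`, `height`,
#'   `s`, `sigma`, `noise_sigma`, `seed`, `classes`, `heatmaps` (per class,
#'   per keypoint type, `ceiling(H/s) x ceiling(W/s)` matrix), `gt` (the
#'   noise-free maps), and `offsets` (per keypoint type, matrices `dx`, `dy`).
#' @export
render_heatmaps <- function(scene, config = render_config()) {
  stopifnot(inherits(scene, "cell_scene"), inherits(config, "render_config"))
  s <- config$s
  hs <- ceiling(scene$height / s)
  ws <- ceiling(scene$width / s)
  zero <- matrix(0, nrow = hs, ncol = ws)
  classes <- scene$classes
  gt <- lapply(stats::setNames(classes, classes), function(cl) {
    lapply(stats::setNames(KEYPOINT_TYPES, KEYPOINT_TYPES), function(tp) zero)
  })
  offsets <- lapply(stats::setNames(KEYPOINT_TYPES, KEYPOINT_TYPES),
                    function(tp) list(dx = zero, dy = zero))

  for (inst in scene$instances) {
    cl <- inst$class
    if (!cl %in% classes) next
    for (tp in KEYPOINT_TYPES) {
      p <- inst$extremes[[tp]]
      if (p[1] < 0 || p[2] < 0 || p[1] >= scene$width || p[2] >= scene$height) {
        abort2(sprintf("keypoint (%g, %g) outside the %d x %d image",
                       p[1], p[2], scene$width, scene$height), "out_of_bounds")
      }
      cx <- floor(p[1] / s); cy <- floor(p[2] / s)
      gt[[cl]][[tp]] <- add_bump(gt[[cl]][[tp]], cx, cy, config$sigma)
      offsets[[tp]]$dx[cy + 1L, cx + 1L] <- p[1] / s - cx
      offsets[[tp]]$dy[cy + 1L, cx + 1L] <- p[2] / s - cy
    }
  }

  heatmaps <- gt
  if (config$noise_sigma > 0 || config$salt_pepper > 0) {
    heatmaps <- with_seed(config$seed, {
      lapply(gt, function(maps) lapply(maps, function(M) {
        if (config$noise_sigma > 0) {
          M <- M + matrix(stats::rnorm(length(M), sd = config$noise_sigma),
                          nrow = nrow(M))
        }
        if (config$salt_pepper > 0) {
          hit <- stats::runif(length(M)) < config$salt_pepper
          M[hit] <- stats::rbinom(sum(hit), 1L, 0.5)
        }
        pmin(pmax(M, 0), 1)
      }))
    })
  }

  structure(list(width = scene$width, height = scene$height, s = s,
                 sigma = config$sigma, noise_sigma = config$noise_sigma,
                 seed = config$seed, classes = classes,
                 heatmaps = heatmaps, gt = gt, offsets = offsets),
            class = "heatmap_bundle")
}

#' @export
print.heatmap_bundle <- function(x, ...) {
  cat(sprintf("<heatmap_bundle> %d x %d px, s = %d (grid %d x %d), sigma %.2f, classes: %s\n",
              x$width, x$height, x$s,
              nrow(x$heatmaps[[1]][[1]]), ncol(x$heatmaps[[1]][[1]]),
              x$sigma, paste(x$classes, collapse = ", ")))
  invisible(x)
}
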