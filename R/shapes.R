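# Parameterized cell-shape boundaries. Four families cover the morphologies
# seen in diagnostic microscopy: round/elliptic nuclei, crescent Toxoplasma,
# spindle Trypanosoma and pear-shaped Babesia.

SHAPE_FAMILIES <- c("ellipse", "crescent", "spindle", "pear")

SHAPE_SIZE_PARAMS <- list(
  ellipse  = c("a", "b"),                           # semi-axes
  crescent = c("outer_r", "inner_r", "offset"),     # disc difference
  spindle  = c("length", "width"),                  # tip-to-tip, mid half-width
  pear     = c("r_big", "r_small", "offset")        # bridged disc union
)

#' Specify one parameterized cell shape
#'
#' @param family one of `"ellipse"`, `"crescent"`, `"spindle"`, `"pear"`.
#' @param center numeric `c(x, y)` position in pixels.
#' @param size named numeric vector of family-specific positive size
#'   parameters (pixels): ellipse `a`,`b` (semi-axes); crescent
#'   `outer_r`,`inner_r`,`offset` (the crescent is the outer disc minus an
#'   inner disc whose center is displaced by `offset`); spindle
#'   `length`,`width` (tip-to-tip length and half-width at the middle); pear
#'   `r_big`,`r_small`,`offset` (two discs bridged by their external
#'   tangents).
#' @param orientation rotation in radians, normalized to `[0, 2*pi)`.
#' @return an object of class `shape_spec`.
#' @examples
#' shape_spec("ellipse", center = c(20, 20), size = c(a = 10, b = 5))
#' @export
shape_spec <- function(family, center = c(0, 0), size, orientation = 0) {
  family <- match.arg(family, SHAPE_FAMILIES)
  wanted <- SHAPE_SIZE_PARAMS[[family]]
  size <- unlist(size)
  if (!all(wanted %in% names(size))) {
    abort2(sprintf("family '%s' needs size parameters: %s", family,
                   paste(wanted, collapse = ", ")), "invalid_parameter")
  }
  size <- size[wanted]
  if (!all(is.finite(size)) || any(size <= 0)) {
    abort2("all size parameters must be positive and finite", "invalid_parameter")
  }
  center <- as.numeric(center)
  stopifnot(length(center) == 2L, all(is.finite(center)))
  orientation <- as.numeric(orientation) %% (2 * pi)
  structure(list(family = family, center = center, size = size,
                 orientation = orientation),
            class = "shape_spec")
}

rotate_translate <- function(xy, orientation, center) {
  co <- cos(orientation); si <- sin(orientation)
  cbind(co * xy[, 1] - si * xy[, 2] + center[1],
        si * xy[, 1] + co * xy[, 2] + center[2])
}

#' Build the boundary polygon of a shape
#'
#' Constructs a closed simple polygon approximating the shape family:
#' parametric ellipse; crescent as the analytic difference of two discs
#' (outer-arc plus inner-arc pieces between the circle intersection points);
#' spindle as two symmetric circular arcs meeting at sharp tips; pear as two
#' discs joined by their external tangent lines. The polygon is rotated by
#' `orientation` and translated to `center`.
#'
#' @param spec a [shape_spec].
#' @param n_vertices number of boundary vertices (>= 16).
#' @return numeric `n x 2` matrix of (x, y) vertices, implicitly closed.
#' @examples
#' poly <- make_shape(shape_spec("ellipse", size = c(a = 10, b = 5)), 64)
#' polygon_area(poly) / (pi * 10 * 5)  # close to 1
#' @export
make_shape <- function(spec, n_vertices = 64L) {
  stopifnot(inherits(spec, "shape_spec"))
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 16L) abort2("n_vertices must be >= 16", "invalid_parameter")
  sz <- spec$size
  base <- switch(spec$family,
    ellipse  = shape_ellipse(sz[["a"]], sz[["b"]], n_vertices),
    crescent = shape_crescent(sz[["outer_r"]], sz[["inner_r"]], sz[["offset"]], n_vertices),
    spindle  = shape_spindle(sz[["length"]], sz[["width"]], n_vertices),
    pear     = shape_pear(sz[["r_big"]], sz[["r_small"]], sz[["offset"]], n_vertices)
  )
  rotate_translate(base, spec$orientation, spec$center)
}

arc_points <- function(cx, cy, r, from, to, n) {
  th <- seq(from, to, length.out = n)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

shape_ellipse <- function(a, b, n) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(a * cos(th), b * sin(th))
}

# Outer disc radius R at the origin minus an inner disc radius r centered at
# (d, 0). Three regimes: discs disjoint (full outer circle), partial overlap
# (two-arc crescent), inner disc swallowed (difference has a hole: invalid).
shape_crescent <- function(R, r, d, n) {
  if (d >= R + r) {
    return(shape_ellipse(R, R, n))  # circle
  }
  if (d + r <= R) {
    abort2("inner disc lies entirely inside the outer disc: crescent is not a simple polygon",
           "invalid_parameter")
  }
  if (d + R <= r) {
    abort2("outer disc lies entirely inside the inner disc: crescent is empty",
           "invalid_parameter")
  }
  x0 <- (d^2 + R^2 - r^2) / (2 * d)
  y0 <- sqrt(max(R^2 - x0^2, 0))
  phi <- atan2(y0, x0)           # outer-circle angle of upper intersection
  psi <- atan2(y0, x0 - d)       # inner-circle angle of upper intersection
  len_out <- R * (2 * pi - 2 * phi)
  len_in <- r * (2 * pi - 2 * psi)
  n_out <- max(8L, round(n * len_out / (len_out + len_in)))
  n_in <- max(8L, n - n_out)
  outer <- arc_points(0, 0, R, phi, 2 * pi - phi, n_out)
  inner <- arc_points(d, 0, r, 2 * pi - psi, psi, n_in + 2L)
  rbind(outer, inner[-c(1L, nrow(inner)), , drop = FALSE])
}

# Two mirrored circular arcs through the tips (+-L/2, 0) and (0, +-w).
shape_spindle <- function(L, w, n) {
  yc <- (w^2 - (L / 2)^2) / (2 * w)   # upper-arc center (0, yc)
  rho <- w - yc
  th1 <- atan2(0 - yc, -L / 2)
  th2 <- atan2(0 - yc, L / 2)
  n_half <- max(8L, n %/% 2L)
  upper <- arc_points(0, yc, rho, th1, th2, n_half + 1L)
  lower <- upper[n_half:2, , drop = FALSE]  # mirrored, tips not repeated
  lower[, 2] <- -lower[, 2]
  rbind(upper, lower)
}

# Big disc radius r1 at the origin, small disc radius r2 at (d, 0), hull
# closed by the external tangent lines touching both circles at angle
# +-alpha, cos(alpha) = (r1 - r2) / d.
shape_pear <- function(r1, r2, d, n) {
  if (r2 > r1) abort2("pear needs r_big >= r_small", "invalid_parameter")
  if (d <= r1 - r2) {
    return(shape_ellipse(r1, r1, n))  # small disc swallowed: plain circle
  }
  alpha <- acos((r1 - r2) / d)
  len_big <- r1 * (2 * pi - 2 * alpha)
  len_small <- r2 * 2 * alpha
  n_big <- max(8L, round((n - 2L) * len_big / (len_big + len_small)))
  n_small <- max(4L, n - 2L - n_big)
  big <- arc_points(0, 0, r1, alpha, 2 * pi - alpha, n_big)
  small <- arc_points(d, 0, r2, 2 * pi - alpha, 2 * pi + alpha, n_small + 2L)
  small <- small[-c(1L, nrow(small)), , drop = FALSE]
  rbind(big, small)
}

#' Extreme points of a polygon
#'
#' Finds the topmost (minimal y), bottommost (maximal y), leftmost (minimal x)
#' and rightmost (maximal x) vertices in image convention (y grows downward),
#' and the induced center `((left.x + right.x)/2, (top.y + bottom.y)/2)`.
#' Ties go to the first vertex in ring order.
#'
#' @param poly numeric `n x 2` polygon (vertices as rows).
#' @return an [extreme_set] with NA responses.
#' @examples
#' extreme_points(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' @export
extreme_points <- function(poly) {
  poly <- as_polygon(poly)
  if (polygon_area(poly) < 1e-9) {
    abort2("degenerate polygon: vertices are collinear or coincident", "degenerate_shape")
  }
  extreme_set(
    top    = poly[which.min(poly[, 2]), ],
    left   = poly[which.min(poly[, 1]), ],
    bottom = poly[which.max(poly[, 2]), ],
    right  = poly[which.max(poly[, 1]), ]
  )
}
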