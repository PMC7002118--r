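# Small polygon primitives used by the scene generator and shape builders.
# Coordinates follow raster conventions throughout the package: x grows
# rightward, y grows downward, continuous pixel units, 0-based pixel indices.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly numeric matrix with two columns (x, y), one vertex per row,
#'   implicitly closed.
#' @return absolute enclosed area in square pixels.
#' @examples
#' polygon_area(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))  # 100
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) {
    abort2("polygon must be an n x 2 matrix with n >= 3", "invalid_input")
  }
  storage.mode(poly) <- "double"
  if (!all(is.finite(poly))) abort2("polygon has non-finite vertices", "invalid_input")
  poly
}

# TRUE when point (x, y) lies inside (or on the boundary of) a simple polygon.
# Even-odd ray casting with an on-edge check.
point_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # on-edge check
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (abs(cross) < 1e-9 &&
        x >= min(xi, xj) - 1e-9 && x <= max(xi, xj) + 1e-9 &&
        y >= min(yi, yj) - 1e-9 && y <= max(yi, yj) + 1e-9) {
      return(TRUE)
    }
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Proper segment intersection (including collinear overlap and endpoint touch).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    abs(d(a, b, c)) < 1e-12 &&
      min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) || on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

# TRUE when two simple polygons touch or overlap (boundary intersection or
# full containment). Quadratic in vertex count; scenes keep polygons small.
polygons_intersect <- function(a, b) {
  a <- as_polygon(a); b <- as_polygon(b)
  # cheap bbox reject
  if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) {
    return(FALSE)
  }
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1L else i + 1L, ]
    for (j in seq_len(nb)) {
      q1 <- b[j, ]; q2 <- b[if (j == nb) 1L else j + 1L, ]
      if (segments_intersect(p1, p2, q1, q2)) return(TRUE)
    }
  }
  point_in_polygon(a[1, 1], a[1, 2], b) || point_in_polygon(b[1, 1], b[1, 2], a)
}
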