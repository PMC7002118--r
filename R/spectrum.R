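# Adjacency-spectrum shape verification. The four extreme points of a cell,
# connected in their cyclic spatial order (top -> right -> bottom -> left),
# form an undirected 4-cycle graph whose edges are weighted by Euclidean
# distance. The sorted eigenvalues of its adjacency matrix — the adjacency
# spectrum — are invariant to rotation, translation and reflection of the
# points and scale linearly with size, which makes them a compact shape
# signature: cross-cell keypoint combinations produce spectra far from those
# of true cells and can be rejected.

SPECTRUM_NODE_ORDER <- c("top", "right", "bottom", "left")

#' Weighted 4-cycle adjacency matrix of an extreme-point set
#'
#' Nodes are ordered (top, right, bottom, left); edges connect spatially
#' adjacent extreme points (top-right, right-bottom, bottom-left, left-top)
#' and are weighted by the Euclidean distance between the two points. The
#' matrix is symmetric with zero diagonal; non-adjacent pairs (the two
#' diagonals) are zero.
#'
#' @param es an [extreme_set], or a list with numeric `top`, `right`,
#'   `bottom`, `left` entries (each `c(x, y)` in pixels).
#' @return a 4x4 symmetric numeric matrix with dimnames in node order.
#' @examples
#' es <- extreme_set(top = c(0, -3), left = c(-4, 0), bottom = c(0, 3), right = c(4, 0))
#' build_adjacency(es)  # all four weights 5
#' @export
build_adjacency <- function(es) {
  pts <- lapply(SPECTRUM_NODE_ORDER, function(nm) {
    p <- as.numeric(es[[nm]])
    if (length(p) != 2L || !all(is.finite(p))) {
      abort2(sprintf("extreme point '%s' must be finite (x, y)", nm), "invalid_input")
    }
    p
  })
  A <- matrix(0, 4, 4, dimnames = list(SPECTRUM_NODE_ORDER, SPECTRUM_NODE_ORDER))
  for (i in 1:4) {
    j <- if (i == 4L) 1L else i + 1L
    w <- sqrt(sum((pts[[i]] - pts[[j]])^2))
    A[i, j] <- w
    A[j, i] <- w
  }
  coincident <- FALSE
  for (i in 1:3) for (j in (i + 1):4) {
    if (all(pts[[i]] == pts[[j]])) coincident <- TRUE
  }
  if (coincident) {
    warning("coincident extreme points: degenerate extreme-point cycle",
            call. = FALSE)
  }
  A
}

#' Adjacency spectrum: sorted eigenvalues of the 4-cycle matrix
#'
#' Solves the characteristic equation `det(lambda I - A) = 0`; for a
#' symmetric matrix all roots are real. Because the graph is a cycle with
#' zero diagonal, the spectrum has zero trace and is symmetric about zero
#' (`lambda1 = -lambda4`, `lambda2 = -lambda3`).
#'
#' @param A a symmetric 4x4 adjacency matrix from [build_adjacency()].
#' @return numeric length-4 vector of eigenvalues, sorted descending (pixels).
#' @examples
#' es <- extreme_set(top = c(0, -5), left = c(-5, 0), bottom = c(0, 5), right = c(5, 0))
#' spectrum_of(build_adjacency(es))  # (2w, 0, 0, -2w) with w = 5 * sqrt(2)
#' @export
spectrum_of <- function(A) {
  A <- as.matrix(A)
  if (!is.numeric(A) || any(dim(A) != c(4L, 4L)) || !all(is.finite(A))) {
    abort2("A must be a finite numeric 4x4 matrix", "invalid_input")
  }
  if (max(abs(A - t(A))) > 1e-9) {
    abort2("A must be symmetric (asymmetry beyond 1e-9)", "invalid_input")
  }
  sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

#' Spectrum of an extreme-point set
#'
#' Convenience composition of [build_adjacency()] and [spectrum_of()], with
#' optional normalization by the total cycle edge length (perimeter of the
#' extreme-point quadrilateral) for magnification-invariant matching.
#'
#' @param es an [extreme_set].
#' @param normalize divide the spectrum by the sum of the four edge weights
#'   (default FALSE: spectra stay in raw pixels, so verification is
#'   size-sensitive).
#' @return numeric length-4 spectrum, sorted descending.
#' @export
extreme_spectrum <- function(es, normalize = FALSE) {
  A <- build_adjacency(es)
  sp <- spectrum_of(A)
  if (normalize) {
    total <- sum(A) / 2
    if (total > 0) sp <- sp / total
  }
  sp
}

#' Euclidean distance between two spectra
#'
#' @param s1,s2 numeric length-4 spectra, sorted descending.
#' @return non-negative float; 0 iff the spectra are equal.
#' @export
spectrum_distance <- function(s1, s2) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  stopifnot(length(s1) == 4L, length(s2) == 4L)
  sqrt(sum((s1 - s2)^2))
}

#' Build a per-class spectrum reference (Spec0) from annotations
#'
#' Computes the adjacency spectrum of every annotated instance of one class,
#' stores them with their elementwise-mean centroid, and derives the cluster
#' radius used to accept or reject candidate detections: `"max"` takes the
#' largest distance from a training spectrum to the centroid, `"quantile"`
#' the `q`-th quantile of those distances; either is then inflated by a
#' tolerance multiplier.
#'
#' @param extreme_sets list of [extreme_set] annotations for one class.
#' @param class class label recorded in the reference.
#' @param radius_rule `"quantile"` (default) or `"max"`.
#' @param q quantile level for the quantile rule (default 0.95).
#' @param multiplier tolerance multiplier applied to the raw radius
#'   (default 1.1).
#' @param normalize store and compare perimeter-normalized spectra.
#' @param mode `"centroid"` verifies against the centroid spectrum;
#'   `"nearest"` against the nearest stored training spectrum.
#' @return an object of class `spectrum_reference`: list with `class`,
#'   `spectra` (n x 4 matrix), `centroid`, `radius`, `rule`, `q`,
#'   `multiplier`, `normalized`, `mode`, `n_train`.
#' @export
build_reference <- function(extreme_sets, class = "cell",
                            radius_rule = c("quantile", "max"),
                            q = 0.95, multiplier = 1.1,
                            normalize = FALSE,
                            mode = c("centroid", "nearest")) {
  radius_rule <- match.arg(radius_rule)
  mode <- match.arg(mode)
  if (!length(extreme_sets)) {
    abort2("need at least one annotated instance to build a reference", "invalid_input")
  }
  stopifnot(q > 0, q <= 1, multiplier > 0)
  spectra <- t(vapply(extreme_sets, extreme_spectrum, numeric(4),
                      normalize = normalize))
  centroid <- colMeans(spectra)
  dists <- sqrt(rowSums(sweep(spectra, 2, centroid)^2))
  raw <- switch(radius_rule,
                max = max(dists),
                quantile = unname(stats::quantile(dists, q, type = 7)))
  structure(list(class = class, spectra = spectra, centroid = centroid,
                 radius = raw * multiplier, rule = radius_rule, q = q,
                 multiplier = multiplier, normalized = normalize,
                 mode = mode, n_train = nrow(spectra)),
            class = "spectrum_reference")
}

#' @export
print.spectrum_reference <- function(x, ...) {
  cat(sprintf("<spectrum_reference> class '%s', %d training spectra, rule %s%s x %.2f\n",
              x$class, x$n_train, x$rule,
              if (x$rule == "quantile") sprintf("(%.2f)", x$q) else "",
              x$multiplier))
  cat(sprintf("  centroid (%s), radius %.4f, %s matching%s\n",
              paste(sprintf("%.3f", x$centroid), collapse = ", "),
              x$radius, x$mode,
              if (x$normalized) ", perimeter-normalized" else ""))
  invisible(x)
}

#' Verify a candidate spectrum against a reference
#'
#' @param candidate numeric length-4 spectrum (normalized the same way the
#'   reference was built; [detect_cells()] handles this automatically).
#' @param ref a `spectrum_reference`.
#' @return list with `accepted` (logical) and `distance` (to the centroid,
#'   or to the nearest stored spectrum in `"nearest"` mode).
#' @export
verify_spectrum <- function(candidate, ref) {
  stopifnot(inherits(ref, "spectrum_reference"))
  candidate <- as.numeric(candidate)
  d <- if (ref$mode == "nearest") {
    min(sqrt(rowSums(sweep(ref$spectra, 2, candidate)^2)))
  } else {
    spectrum_distance(candidate, ref$centroid)
  }
  list(accepted = d <= ref$radius, distance = d)
}
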