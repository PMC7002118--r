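#' Extreme-point set of one cell candidate
#'
#' Bundles the five characteristic points of a cell — the topmost, leftmost,
#' bottommost and rightmost boundary points plus the geometric center — with
#' the heatmap responses observed at each point (NA for ground-truth
#' annotations, where no heatmap was decoded).
#'
#' Image conventions: x grows rightward, y grows downward, continuous pixel
#' units. "Top" is therefore the point of minimal y.
#'
#' @param top,left,bottom,right numeric length-2 vectors `c(x, y)` in pixels.
#' @param center optional `c(x, y)`; defaults to
#'   `((left.x + right.x) / 2, (top.y + bottom.y) / 2)`.
#' @param responses named numeric vector of heatmap responses for
#'   `c(top, left, bottom, right, center)`; defaults to NA.
#' @return an object of class `extreme_set`.
#' @examples
#' es <- extreme_set(top = c(5, 0), left = c(0, 5), bottom = c(5, 10), right = c(10, 5))
#' es$center  # c(5, 5)
#' @export
extreme_set <- function(top, left, bottom, right, center = NULL, responses = NULL) {
  pts <- list(top = top, left = left, bottom = bottom, right = right)
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 2L || !all(is.finite(p))) {
      abort2(sprintf("'%s' must be a finite length-2 (x, y) vector", nm), "invalid_input")
    }
    pts[[nm]] <- p
  }
  if (is.null(center)) {
    center <- c((pts$left[1] + pts$right[1]) / 2, (pts$top[2] + pts$bottom[2]) / 2)
  }
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center))) {
    abort2("'center' must be a finite length-2 (x, y) vector", "invalid_input")
  }
  if (is.null(responses)) {
    responses <- c(top = NA_real_, left = NA_real_, bottom = NA_real_,
                   right = NA_real_, center = NA_real_)
  } else {
    responses <- responses[c("top", "left", "bottom", "right", "center")]
    names(responses) <- c("top", "left", "bottom", "right", "center")
  }
  structure(
    c(pts, list(center = center, responses = responses)),
    class = "extreme_set"
  )
}

#' @export
print.extreme_set <- function(x, ...) {
  cat("<extreme_set>\n")
  for (nm in c("top", "left", "bottom", "right", "center")) {
    cat(sprintf("  %-6s (%8.3f, %8.3f)  response %s\n", nm,
                x[[nm]][1], x[[nm]][2],
                ifelse(is.na(x$responses[[nm]]), "NA",
                       sprintf("%.4f", x$responses[[nm]]))))
  }
  invisible(x)
}

#' Axis-aligned bounding box of an extreme-point set
#'
#' @param es an [extreme_set].
#' @return numeric `c(xmin, ymin, xmax, ymax)` in pixels:
#'   `[left.x, top.y, right.x, bottom.y]`.
#' @export
extreme_box <- function(es) {
  stopifnot(inherits(es, "extreme_set"))
  c(es$left[1], es$top[2], es$right[1], es$bottom[2])
}
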