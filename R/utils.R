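# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' package operations never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stop with a classed condition so callers/tests can match on error class.
abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "extremecell_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Nearest grid cell with round-half-down tie rule (0-based cells).
# ceiling(x - 0.5) maps 2.5 -> 2, 2.51 -> 3.
nearest_cell <- function(x) as.integer(ceiling(x - 0.5))

`%||%` <- function(a, b) if (is.null(a)) b else a
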