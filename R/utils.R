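# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded package
#' internals never disturb user-level random streams. A `NULL` seed means
#' "use the current stream".
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive n reproducible substream seeds (kept within 32-bit integer range).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a classed condition so callers can catch over-shrinkage
# distinctly from ordinary errors.
stopOvershrunk <- function(delta, component) {
  cond <- structure(
    class = c("stplsOvershrunk", "error", "condition"),
    list(
      message = sprintf(
        "soft-thresholding at delta = %g removed every weight in component %d",
        delta, component),
      call = sys.call(-1),
      delta = delta,
      component = component
    )
  )
  stop(cond)
}

assertMatrixLike <- function(x, what = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", what))
  }
  invisible(x)
}
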