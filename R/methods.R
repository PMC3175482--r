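# Accessors, coercions and show() methods.

#' @describeIn GenotypeMatrix the distance matrix itself.
#' @param x,object a `GenotypeMatrix`.
#' @export
setMethod("distMatrix", "GenotypeMatrix", function(x) x@X)

#' @describeIn GenotypeMatrix gene ids removed by the all-below filter.
#' @export
setMethod("discardedGenes", "GenotypeMatrix", function(x) x@discarded)

#' @describeIn GenotypeMatrix the saturation distance cap.
#' @export
setMethod("distanceCap", "GenotypeMatrix", function(x) x@dMax)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@X))

#' @export
setMethod("dimnames", "GenotypeMatrix", function(x) dimnames(x@X))

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d genomes x %d genes (%d discarded by the %.2f filter)\n",
    nrow(object@X), ncol(object@X), length(object@discarded),
    object@filterThreshold))
  cat(sprintf("  distances in [0, %.4f], normalized-score floor %.3g\n",
              object@dMax, object@lowerBound))
})

#' @export
as.matrix.GenotypeMatrix <- function(x, ...) x@X

#' @describeIn STPLSModel genes with nonzero coefficients.
#' @export
setMethod("selectedGenes", "STPLSModel", function(x) x@selected)

#' @describeIn STPLSModel the shrinkage level delta.
#' @export
setMethod("shrinkage", "STPLSModel", function(x) x@delta)

#' @describeIn STPLSModel number of fitted components.
#' @export
setMethod("nComponents", "STPLSModel", function(x) x@ncomp)

#' @describeIn STPLSModel sparse loading-weight matrix W (p x k).
#' @export
setMethod("plsWeights", "STPLSModel", function(x) x@weights)

#' @describeIn STPLSModel X-loading matrix P (p x k).
#' @export
setMethod("plsLoadings", "STPLSModel", function(x) x@xLoadings)

#' @describeIn STPLSModel score matrix T (n x k).
#' @export
setMethod("plsScores", "STPLSModel", function(x) x@scores)

#' @describeIn STPLSModel y-loading vector q.
#' @export
setMethod("yLoadings", "STPLSModel", function(x) x@yLoadings)

#' @describeIn STPLSModel regression coefficients on the standardized scale;
#'   `ncomp` retrieves the coefficients of a smaller-component model from the
#'   coefficient path.
#' @param ncomp number of components; defaults to the fitted number.
#' @param ... ignored.
#' @export
setMethod("coef", "STPLSModel", function(object, ncomp = NULL, ...) {
  k <- as.integer(ncomp %||% object@ncomp)
  if (k < 1L || k > object@ncomp) {
    stop(sprintf("ncomp must be in 1..%d", object@ncomp))
  }
  stats::setNames(object@coefPath[, k], names(object@coefficients))
})

#' @export
setMethod("show", "STPLSModel", function(object) {
  cat(sprintf(
    "STPLSModel: %d component%s, delta = %.3g, %d of %d genes selected%s\n",
    object@ncomp, if (object@ncomp == 1L) "" else "s", object@delta,
    length(object@selected), length(object@coefficients),
    if (object@truncated) " (truncated: over-shrunk)" else ""))
})

#' @describeIn STPLSCV the grid as a data.frame.
#' @param x,object an `STPLSCV`.
#' @export
setMethod("cvTable", "STPLSCV", function(x) x@grid)

#' @export
setMethod("show", "STPLSCV", function(object) {
  g <- object@grid
  cat(sprintf(
    "STPLSCV: %d x %d grid, %d segments of ~%d samples (%d invalid cells)\n",
    length(object@kGrid), length(object@deltaGrid), length(object@segments),
    object@segmentSize, sum(!g$valid)))
  if (any(g$valid)) {
    i <- which(g$valid)[which.min(g$cvrmse[g$valid])]
    cat(sprintf("  minimum CVRMSE %.4f at k = %d, delta = %.3g\n",
                g$cvrmse[i], g$k[i], g$delta[i]))
  }
})

#' @describeIn STPLSChoice the refit final model.
#' @param x,object an `STPLSChoice`.
#' @export
setMethod("chosenModel", "STPLSChoice", function(x) x@model)

#' @describeIn STPLSChoice genes selected by the final model.
#' @export
setMethod("selectedGenes", "STPLSChoice", function(x) x@model@selected)

#' @export
setMethod("show", "STPLSChoice", function(object) {
  cat(sprintf(
    "STPLSChoice: k = %d, delta = %.3g (CVRMSE %.4f <= bound %.4f)\n",
    object@k, object@delta, object@cvrmse, object@slackBound))
  cat(sprintf("  cross-validated d-index %.4f; %d genes selected%s\n",
              object@dIndex, length(object@model@selected),
              if (object@relaxed) "; minimum-gene constraint relaxed" else ""))
})
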