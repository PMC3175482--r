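#' GenotypeMatrix: evolutionary-distance genotype features
#'
#' An n (genomes) x p (reference genes) matrix of approximate evolutionary
#' distances from the reference genome, produced by [buildGenotypeMatrix()].
#' Columns are the reference genes that survived the all-below-threshold
#' filter; `discarded` records the ones that did not. Distances are capped
#' at `dMax`, the saturation value implied by the epsilon floor inside the
#' Jukes-Cantor transform.
#'
#' @slot X numeric matrix of distances with genome rownames and gene colnames.
#' @slot discarded character vector of filtered-out gene ids.
#' @slot dMax numeric(1), the distance cap.
#' @slot lowerBound numeric(1), the normalized-score floor (default 1/20).
#' @slot filterThreshold numeric(1), the all-below filter threshold.
#'
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(
    X = "matrix",
    discarded = "character",
    dMax = "numeric",
    lowerBound = "numeric",
    filterThreshold = "numeric"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  X <- object@X
  if (!is.numeric(X)) msg <- c(msg, "X must be numeric")
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    msg <- c(msg, "X must carry genome rownames and gene colnames")
  } else {
    if (anyDuplicated(rownames(X))) msg <- c(msg, "duplicated genome ids")
    if (anyDuplicated(colnames(X))) msg <- c(msg, "duplicated gene ids")
  }
  if (length(object@dMax) != 1L || !is.finite(object@dMax)) {
    msg <- c(msg, "dMax must be a single finite number")
  }
  if (length(X) && (any(!is.finite(X)) ||
                    any(X < -1e-12) ||
                    any(X > object@dMax + 1e-8))) {
    msg <- c(msg, "distances must be finite and within [0, dMax]")
  }
  if (length(intersect(object@discarded, colnames(X)))) {
    msg <- c(msg, "discarded genes must not appear among the columns")
  }
  if (length(msg)) msg else TRUE
})

#' STPLSModel: a fitted soft-thresholding PLS regression model
#'
#' Holds the loading weights, loadings, scores and regression coefficients
#' of an ST-PLS fit for a single phenotype, on the standardized scale,
#' together with the column standardization parameters needed to predict
#' new samples on the original scale. The selected gene set is the support
#' of the coefficient vector.
#'
#' @slot delta numeric(1) shrinkage level in [0, 1).
#' @slot ncomp integer(1) number of fitted components.
#' @slot weights p x k matrix of sparse unit-norm loading weights (W).
#' @slot xLoadings p x k matrix of X-loadings (P).
#' @slot yLoadings numeric(k) y-loadings (q).
#' @slot scores n x k matrix of component scores (T).
#' @slot coefPath p x k matrix; column a holds the coefficient vector of the
#'   a-component model, so the last column equals `coefficients`.
#' @slot coefficients named numeric(p) regression coefficients (standardized
#'   scale).
#' @slot xCenter,xScale named numeric(p) column standardization of X.
#' @slot yCenter,yScale numeric(1) standardization of y.
#' @slot selected character, genes with nonzero coefficients.
#' @slot truncated logical(1), TRUE when soft-thresholding removed all
#'   weights before the requested number of components was reached.
#'
#' @aliases STPLSModel
#' @exportClass STPLSModel
setClass("STPLSModel",
  slots = c(
    delta = "numeric",
    ncomp = "integer",
    weights = "matrix",
    xLoadings = "matrix",
    yLoadings = "numeric",
    scores = "matrix",
    coefPath = "matrix",
    coefficients = "numeric",
    xCenter = "numeric",
    xScale = "numeric",
    yCenter = "numeric",
    yScale = "numeric",
    selected = "character",
    truncated = "logical"
  )
)

setValidity("STPLSModel", function(object) {
  msg <- character(0)
  W <- object@weights
  k <- object@ncomp
  if (k < 1L) msg <- c(msg, "at least one component is required")
  if (ncol(W) != k) msg <- c(msg, "weights must have ncomp columns")
  if (object@delta < 0 || object@delta >= 1) {
    msg <- c(msg, "delta must lie in [0, 1)")
  }
  if (ncol(W) >= 1L) {
    nrm <- sqrt(colSums(W^2))
    if (any(abs(nrm - 1) > 1e-8)) {
      msg <- c(msg, "weight columns must have unit norm")
    }
    if (ncol(W) > 1L) {
      G <- crossprod(W)
      if (max(abs(G[upper.tri(G)])) > 1e-8) {
        msg <- c(msg, "weight columns must be mutually orthogonal")
      }
    }
  }
  sel <- names(object@coefficients)[object@coefficients != 0]
  if (!setequal(sel, object@selected)) {
    msg <- c(msg, "selected must equal the support of the coefficients")
  }
  if (length(msg)) msg else TRUE
})

#' STPLSCV: a cross-validation grid over components and shrinkage levels
#'
#' Result of [crossValidate()]: one cell per (components, delta) pair, with
#' the pooled cross-validated RMSE, its standard error over segments, the
#' mean selected-gene count across folds, a validity flag (a cell is invalid
#' when soft-thresholding over-shrank in at least one fold), and the pooled
#' out-of-fold predictions used for the d-index.
#'
#' @slot grid data.frame with columns k, delta, cvrmse, se, meanGenes, valid.
#' @slot predictions n x ncell matrix of pooled out-of-fold predictions.
#' @slot segments list of integer row indices, the leave-out segments.
#' @slot X,y the training data (kept so that [selectModel()] can refit).
#' @slot kGrid,deltaGrid,segmentSize,seed the settings of the run.
#'
#' @aliases STPLSCV
#' @exportClass STPLSCV
setClass("STPLSCV",
  slots = c(
    grid = "data.frame",
    predictions = "matrix",
    segments = "list",
    X = "matrix",
    y = "numeric",
    kGrid = "integer",
    deltaGrid = "numeric",
    segmentSize = "integer",
    seed = "numeric"
  )
)

setValidity("STPLSCV", function(object) {
  msg <- character(0)
  g <- object@grid
  need <- c("k", "delta", "cvrmse", "se", "meanGenes", "valid")
  if (!all(need %in% names(g))) {
    msg <- c(msg, "grid must have columns k, delta, cvrmse, se, meanGenes, valid")
  } else {
    if (any(g$cvrmse[g$valid] < 0, na.rm = TRUE)) {
      msg <- c(msg, "CVRMSE must be non-negative")
    }
  }
  lo <- sort(unlist(object@segments))
  if (!identical(lo, seq_len(nrow(object@X)))) {
    msg <- c(msg, "segments must partition the sample rows")
  }
  if (length(msg)) msg else TRUE
})

#' STPLSChoice: the model chosen by the two-standard-error slack rule
#'
#' Result of [selectModel()]: the chosen grid cell, the slack bound it had
#' to satisfy, the refit on all samples, and the d-index of the pooled
#' cross-validated predictions at the chosen cell.
#'
#' @slot k integer(1) chosen number of components.
#' @slot delta numeric(1) chosen shrinkage level.
#' @slot cvrmse numeric(1) CVRMSE of the chosen cell.
#' @slot minCvrmse numeric(1) grid-minimum CVRMSE.
#' @slot slackBound numeric(1) minimum CVRMSE plus the slack.
#' @slot dIndex numeric(1) index of agreement of pooled CV predictions.
#' @slot model the final [STPLSModel-class] refit on all samples.
#' @slot relaxed logical(1), TRUE when the minimum-gene constraint had to be
#'   dropped.
#'
#' @aliases STPLSChoice
#' @exportClass STPLSChoice
setClass("STPLSChoice",
  slots = c(
    k = "integer",
    delta = "numeric",
    cvrmse = "numeric",
    minCvrmse = "numeric",
    slackBound = "numeric",
    dIndex = "numeric",
    model = "STPLSModel",
    relaxed = "logical"
  )
)

setValidity("STPLSChoice", function(object) {
  if (object@cvrmse > object@slackBound + 1e-12) {
    "chosen cell violates the slack inequality"
  } else TRUE
})
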