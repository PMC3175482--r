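# Soft-Thresholding PLS regression (ST-PLS) for one phenotype.
#
# The model is the linear regression E(y) = X beta fitted by an
# orthogonal-scores NIPALS PLS1 recursion in which every loading-weight
# vector is sparsified before use: the weights are scaled to max |w| = 1,
# soft-thresholded by delta, re-orthogonalized against earlier weight
# vectors and normalized to unit length. Genes whose weight survives in at
# least one component acquire nonzero regression coefficients, so fitting
# and variable selection happen simultaneously; larger delta gives a
# smaller selected gene set.

#' Soft-thresholding update of a PLS loading-weight vector
#'
#' Applies, in order: (i) scaling `w <- w / max |w_j|`; (ii)
#' soft-thresholding `w_j <- sign(w_j) (|w_j| - delta)_+`; (iii)
#' Gram-Schmidt orthogonalization against previously accepted weight
#' vectors (a no-op for the first component); (iv) normalization to unit
#' length.
#'
#' @param w numeric weight vector (not all zero).
#' @param delta shrinkage level in \[0, 1).
#' @param Wprev p x (a - 1) matrix of earlier orthonormal weight vectors,
#'   or `NULL` for the first component.
#' @return unit-norm vector orthogonal to the columns of `Wprev`.
#'
#' Over-shrinkage (all weights removed) raises a condition of class
#' `stplsOvershrunk` carrying the offending `delta` and component number;
#' model selection treats the affected grid cells as invalid.
#' @export
#' @examples
#' stWeightUpdate(c(0.5, -1, 0.25), delta = 0.3)
stWeightUpdate <- function(w, delta, Wprev = NULL) {
  if (!is.numeric(w) || !length(w) || any(!is.finite(w))) {
    stop("'w' must be a finite numeric vector")
  }
  if (all(w == 0)) stop("'w' must not be all zero")
  if (length(delta) != 1L || delta < 0 || delta >= 1) {
    stop("'delta' must lie in [0, 1)")
  }
  comp <- if (is.null(Wprev)) 1L else ncol(Wprev) + 1L
  w <- w / max(abs(w))
  w <- sign(w) * pmax(abs(w) - delta, 0)
  if (all(w == 0)) stopOvershrunk(delta, comp)
  if (!is.null(Wprev) && ncol(Wprev)) {
    w <- w - Wprev %*% crossprod(Wprev, w)
    w <- as.numeric(w)
  }
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12) stopOvershrunk(delta, comp)
  w / nrm
}

#' Fit an ST-PLS regression model
#'
#' X and y are centred and standardized (sample sd) internally. For each
#' component a, the weight `w_a = E_a' f_a` of the deflated data is
#' sparsified with [stWeightUpdate()]; scores, loadings and deflation then
#' follow the orthogonal-scores NIPALS PLS1 recursion
#' (`t_a = E_a w_a`, `p_a = E_a' t_a / t_a't_a`, `q_a = f_a' t_a / t_a't_a`,
#' `E_{a+1} = E_a - t_a p_a'`, `f_{a+1} = f_a - t_a q_a`), and the
#' regression coefficients are `beta = W (P' W)^{-1} q` on the
#' standardized scale.
#'
#' If soft-thresholding removes every weight at some component a > 1 the
#' model is returned truncated at component a - 1 and flagged; if it
#' happens at the first component an `stplsOvershrunk` error is raised.
#' Zero-variance columns of X are centred but not scaled; their weights
#' and coefficients are exactly zero.
#'
#' @param X n x p numeric matrix with gene colnames (and, ideally, strain
#'   rownames).
#' @param y numeric response of length n; if named, it is aligned to the
#'   rownames of `X`.
#' @param ncomp number of components k (1 <= k <= n - 1).
#' @param delta shrinkage level in \[0, 1); 0 recovers standard PLS1.
#' @return An [STPLSModel-class].
#' @export
stpls <- function(X, y, ncomp = 1L, delta = 0) {
  X <- as.matrix(X)
  assertMatrixLike(X, "X")
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("at least 3 samples are required")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > n - 1L) stop("'ncomp' must be in 1..(n - 1)")
  if (length(delta) != 1L || delta < 0 || delta >= 1) {
    stop("'delta' must lie in [0, 1)")
  }
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!setequal(names(y), rownames(X))) {
      stop("row labels of 'X' and names of 'y' disagree")
    }
    y <- y[rownames(X)]
  }
  if (length(y) != n) stop("'y' must have one value per row of 'X'")
  if (anyNA(X) || anyNA(y)) stop("'X' and 'y' must not contain NA")
  genes <- colnames(X) %||% paste0("V", seq_len(p))

  xCenter <- colMeans(X)
  xScale <- apply(X, 2L, stats::sd)
  xScale[xScale == 0] <- 1  # centred constant columns are all-zero: inert
  E <- sweep(sweep(X, 2L, xCenter, "-"), 2L, xScale, "/")
  yCenter <- mean(y)
  yScale <- stats::sd(y)
  if (yScale == 0) stop("'y' is constant")
  f <- (y - yCenter) / yScale

  W <- P <- matrix(0, p, 0L)
  Tm <- matrix(0, n, 0L)
  q <- numeric(0)
  coefPath <- matrix(0, p, 0L)
  truncated <- FALSE

  for (a in seq_len(ncomp)) {
    w <- as.numeric(crossprod(E, f))
    res <- tryCatch(
      stWeightUpdate(w, delta, if (ncol(W)) W else NULL),
      stplsOvershrunk = function(e) e
    )
    if (inherits(res, "stplsOvershrunk")) {
      if (a == 1L) stop(res)
      truncated <- TRUE
      break
    }
    t <- as.numeric(E %*% res)
    tt <- sum(t^2)
    if (tt < 1e-24) { truncated <- TRUE; break }
    pa <- as.numeric(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pa)
    f <- f - t * qa
    W <- cbind(W, res); P <- cbind(P, pa); Tm <- cbind(Tm, t)
    q <- c(q, qa)
    beta <- tryCatch(
      as.numeric(W %*% solve(crossprod(P, W), q)),
      error = function(e) stop("singular P'W system: ", conditionMessage(e))
    )
    coefPath <- cbind(coefPath, beta)
  }
  k <- ncol(W)
  dimnames(W) <- dimnames(P) <- list(genes, paste0("comp", seq_len(k)))
  dimnames(Tm) <- list(rownames(X), paste0("comp", seq_len(k)))
  dimnames(coefPath) <- list(genes, paste0("comp", seq_len(k)))
  beta <- stats::setNames(coefPath[, k], genes)
  methods::new("STPLSModel",
    delta = delta, ncomp = k, weights = W, xLoadings = P,
    yLoadings = q, scores = Tm, coefPath = coefPath, coefficients = beta,
    xCenter = stats::setNames(xCenter, genes),
    xScale = stats::setNames(xScale, genes),
    yCenter = yCenter, yScale = yScale,
    selected = genes[beta != 0], truncated = truncated)
}

#' Predict phenotype values from an ST-PLS model
#'
#' Standardizes `newdata` columns with the training parameters, applies
#' the coefficient vector, and back-transforms to the original response
#' scale. Columns are matched by gene label; missing or extra columns are
#' an error.
#'
#' @param object an [STPLSModel-class].
#' @param newdata m x p matrix with the training gene columns.
#' @param ncomp number of components to use (defaults to all fitted ones).
#' @return numeric vector of m predictions.
#' @export
setMethod("predict", "STPLSModel", function(object, newdata, ncomp = NULL) {
  newdata <- as.matrix(newdata)
  genes <- names(object@coefficients)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(genes)) {
      stop("'newdata' must have the training gene columns")
    }
    colnames(newdata) <- genes
  }
  missing <- setdiff(genes, colnames(newdata))
  extra <- setdiff(colnames(newdata), genes)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "column mismatch: missing [%s], extra [%s]",
      paste(utils::head(missing, 5L), collapse = ", "),
      paste(utils::head(extra, 5L), collapse = ", ")))
  }
  newdata <- newdata[, genes, drop = FALSE]
  Z <- sweep(sweep(newdata, 2L, object@xCenter, "-"), 2L, object@xScale, "/")
  b <- coef(object, ncomp = ncomp)
  as.numeric(Z %*% b) * object@yScale + object@yCenter
})
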