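# Model selection: leave-3-out cross-validation over a (components x
# shrinkage) grid, the two-standard-error slack rule with a minimum-gene
# constraint, the index-of-agreement d statistic, and permutation null
# distributions obtained by reshuffling the rows of X.

# The shrinkage grid used throughout.
defaultDeltaGrid <- function() seq(0.70, 0.97, by = 0.03)

#' Index of agreement (d statistic)
#'
#' Willmott's index of agreement
#' `d = 1 - sum((p_i - o_i)^2) / sum((|p_i - obar| + |o_i - obar|)^2)`,
#' ranging from 0 (complete disagreement; in particular, a constant
#' prediction at the observed mean) to 1 (perfect agreement).
#'
#' @param obs observed values (length >= 2, not constant).
#' @param pred predicted values, same length.
#' @return a number in \[0, 1\].
#' @export
#' @examples
#' dIndex(c(1, 2, 3), c(1, 2, 3))        # 1
#' dIndex(c(1, 2, 3), rep(2, 3))         # 0
dIndex <- function(obs, pred) {
  if (length(obs) < 2L || length(obs) != length(pred)) {
    stop("'obs' and 'pred' must have equal length >= 2")
  }
  if (anyNA(obs) || anyNA(pred)) stop("missing values in 'obs' or 'pred'")
  ob <- mean(obs)
  if (all(obs == ob)) stop("'obs' is constant: d-index undefined")
  den <- sum((abs(pred - ob) + abs(obs - ob))^2)
  1 - sum((pred - obs)^2) / den
}

#' Cross-validate ST-PLS over a components x shrinkage grid
#'
#' Random leave-`segmentSize`-out cross-validation: the samples are
#' partitioned (seeded) into `floor(n / segmentSize)` disjoint segments,
#' the last absorbing any remainder. For every segment the model is fitted
#' on the complement at each shrinkage level (standardization happens
#' inside the fold, so held-out rows only ever see training-fold
#' parameters) and the left-out samples are predicted at every component
#' count. Pooled squared errors give the CVRMSE per cell; its standard
#' error is the sd of per-segment RMSEs divided by sqrt(#segments). A cell
#' is invalid when soft-thresholding over-shrank in at least one fold.
#'
#' @param X n x p genotype matrix (a [GenotypeMatrix-class] or plain
#'   matrix).
#' @param y numeric response of length n.
#' @param kGrid component counts to evaluate; default 1:10.
#' @param deltaGrid shrinkage levels; default 0.70, 0.73, ..., 0.97.
#' @param segmentSize samples per left-out segment; default 3.
#' @param seed seed for the random partition (optional).
#' @return An [STPLSCV-class].
#' @export
crossValidate <- function(X, y, kGrid = 1:10, deltaGrid = defaultDeltaGrid(),
                          segmentSize = 3L, seed = NULL) {
  if (methods::is(X, "GenotypeMatrix")) X <- distMatrix(X)
  X <- as.matrix(X)
  assertMatrixLike(X, "X")
  n <- nrow(X)
  kGrid <- sort(unique(as.integer(kGrid)))
  deltaGrid <- sort(unique(as.numeric(deltaGrid)))
  if (!length(kGrid) || !length(deltaGrid)) stop("empty grid")
  segmentSize <- as.integer(segmentSize)
  nSeg <- n %/% segmentSize
  if (nSeg < 2L) stop("too few samples for the requested segment size")
  if (max(kGrid) > n - segmentSize - 1L) {
    stop("largest component count exceeds what a training fold supports")
  }
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!setequal(names(y), rownames(X))) {
      stop("row labels of 'X' and names of 'y' disagree")
    }
    y <- y[rownames(X)]
  }

  perm <- withSeed(seed, sample.int(n))
  sizes <- c(rep(segmentSize, nSeg - 1L), n - (nSeg - 1L) * segmentSize)
  segments <- split(perm, rep(seq_len(nSeg), times = sizes))
  names(segments) <- NULL

  cells <- expand.grid(k = kGrid, delta = deltaGrid,
                       KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells)
  pred <- matrix(NA_real_, n, nc)
  nsel <- matrix(NA_real_, nSeg, nc)
  foldOk <- matrix(FALSE, nSeg, nc)
  kMax <- max(kGrid)

  for (s in seq_len(nSeg)) {
    test <- segments[[s]]
    Xtr <- X[-test, , drop = FALSE]
    ytr <- y[-test]
    Xte <- X[test, , drop = FALSE]
    for (d in deltaGrid) {
      fit <- tryCatch(stpls(Xtr, unname(ytr), ncomp = kMax, delta = d),
                      stplsOvershrunk = function(e) NULL)
      idx <- which(cells$delta == d)
      if (is.null(fit)) next
      for (i in idx) {
        kk <- cells$k[i]
        if (kk > fit@ncomp) next
        pred[test, i] <- predict(fit, Xte, ncomp = kk)
        nsel[s, i] <- sum(fit@coefPath[, kk] != 0)
        foldOk[s, i] <- TRUE
      }
    }
  }

  valid <- apply(foldOk, 2L, all)
  cvrmse <- se <- rep(NA_real_, nc)
  for (i in which(valid)) {
    err <- pred[, i] - y
    cvrmse[i] <- sqrt(mean(err^2))
    segRmse <- vapply(segments, function(ix) sqrt(mean(err[ix]^2)), numeric(1))
    se[i] <- stats::sd(segRmse) / sqrt(nSeg)
  }
  grid <- data.frame(
    k = cells$k, delta = cells$delta, cvrmse = cvrmse, se = se,
    meanGenes = colMeans(nsel), valid = valid
  )
  methods::new("STPLSCV",
    grid = grid, predictions = pred, segments = segments,
    X = X, y = as.numeric(y), kGrid = kGrid, deltaGrid = deltaGrid,
    segmentSize = segmentSize,
    seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Choose a grid cell by the two-standard-error slack rule
#'
#' Candidate cells are the valid ones whose CVRMSE is at most the grid
#' minimum plus `slackSE` standard errors of the minimum cell and whose
#' mean selected-gene count is at least `minGenes`. Among candidates the
#' largest shrinkage level wins (ties broken by the smallest component
#' count), trading a little prediction error for a sparser, simpler model.
#' If no candidate reaches `minGenes` the constraint is dropped with a
#' warning and the slack rule alone decides. The chosen cell is refit on
#' all samples, and the d-index of its pooled cross-validated predictions
#' is recorded.
#'
#' @param cv an [STPLSCV-class] from [crossValidate()].
#' @param slackSE slack multiplier; default 2.
#' @param minGenes minimum mean selected-gene count; default 25.
#' @return An [STPLSChoice-class].
#' @export
selectModel <- function(cv, slackSE = 2, minGenes = 25) {
  stopifnot(methods::is(cv, "STPLSCV"))
  g <- cv@grid
  if (!any(g$valid)) stop("no valid cells in the cross-validation grid")
  vi <- which(g$valid)
  i0 <- vi[which.min(g$cvrmse[vi])]
  bound <- g$cvrmse[i0] + slackSE * g$se[i0]
  cand <- g$valid & g$cvrmse <= bound & g$meanGenes >= minGenes
  relaxed <- FALSE
  if (!any(cand)) {
    warning(sprintf(
      "no cell within slack reaches %d genes on average; dropping the minimum-gene constraint",
      as.integer(minGenes)))
    relaxed <- TRUE
    cand <- g$valid & g$cvrmse <= bound
  }
  pick <- which(cand)
  pick <- pick[order(-g$delta[pick], g$k[pick])][1L]
  model <- suppressWarnings(
    stpls(cv@X, cv@y, ncomp = g$k[pick], delta = g$delta[pick])
  )
  methods::new("STPLSChoice",
    k = as.integer(g$k[pick]), delta = g$delta[pick],
    cvrmse = g$cvrmse[pick], minCvrmse = g$cvrmse[i0], slackBound = bound,
    dIndex = dIndex(cv@y, cv@predictions[, pick]),
    model = model, relaxed = relaxed)
}

#' Permutation null distribution of the selection pipeline
#'
#' For each permutation the rows of X are reshuffled (breaking the
#' genotype-phenotype linkage while preserving the correlation structure
#' among genes), the full cross-validation + slack-rule selection + refit
#' pipeline is rerun, and the cross-validated d-index and selected-gene
#' count of the chosen model are recorded. All randomness derives from
#' `seed` through per-permutation substreams. An explicit list of row
#' orders can be injected through `permutations` (the identity order then
#' reproduces the unpermuted pipeline run at the same seed).
#'
#' @inheritParams crossValidate
#' @inheritParams selectModel
#' @param nPerm number of permutations.
#' @param permutations optional list of integer row orders overriding the
#'   random ones; when given, the cross-validation partition uses `seed`
#'   directly for every permutation.
#' @return data.frame with one row per permutation: `dIndex`,
#'   `nSelected`, `failed`.
#' @export
permutationNull <- function(X, y, nPerm = 99L, seed = NULL,
                            kGrid = 1:10, deltaGrid = defaultDeltaGrid(),
                            segmentSize = 3L, slackSE = 2, minGenes = 25,
                            permutations = NULL) {
  if (methods::is(X, "GenotypeMatrix")) X <- distMatrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is.null(permutations)) {
    nPerm <- length(permutations)
    permSeeds <- rep(NA_integer_, nPerm)
    cvSeeds <- rep(if (is.null(seed)) NA_integer_ else as.integer(seed), nPerm)
  } else {
    ss <- deriveSeeds(seed, 2L * nPerm)
    permSeeds <- ss[seq_len(nPerm)]
    cvSeeds <- ss[nPerm + seq_len(nPerm)]
  }
  dI <- nSel <- rep(NA_real_, nPerm)
  failed <- rep(FALSE, nPerm)
  for (b in seq_len(nPerm)) {
    perm <- if (!is.null(permutations)) {
      as.integer(permutations[[b]])
    } else {
      withSeed(permSeeds[b], sample.int(n))
    }
    Xp <- X[perm, , drop = FALSE]
    rownames(Xp) <- rownames(X)
    res <- tryCatch({
      cv <- crossValidate(Xp, unname(y), kGrid = kGrid,
                          deltaGrid = deltaGrid, segmentSize = segmentSize,
                          seed = if (is.na(cvSeeds[b])) NULL else cvSeeds[b])
      ch <- suppressWarnings(selectModel(cv, slackSE = slackSE,
                                         minGenes = minGenes))
      c(ch@dIndex, length(ch@model@selected))
    }, error = function(e) NULL)
    if (is.null(res)) failed[b] <- TRUE
    else { dI[b] <- res[1L]; nSel[b] <- res[2L] }
  }
  data.frame(perm = seq_len(nPerm), dIndex = dI, nSelected = nSel,
             failed = failed)
}
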