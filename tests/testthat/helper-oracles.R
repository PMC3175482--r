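# Independent oracles and small fixture builders used across the tests.
# These deliberately re-derive results through different routes than the
# package code (textbook NIPALS, combinatorial sums, brute-force loops).

# Textbook orthogonal-scores NIPALS PLS1 with unit-norm weights, fitted on
# internally standardized data; returns the coefficient matrix (one column
# per component count) on the standardized scale.
plsOracleCoefPath <- function(X, y, k) {
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  E <- Xs
  f <- ys
  W <- P <- NULL
  q <- numeric(0)
  out <- matrix(0, ncol(X), k)
  for (a in seq_len(k)) {
    w <- as.numeric(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    p <- as.numeric(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * qa
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qa)
    out[, a] <- W %*% solve(t(P) %*% W) %*% q
  }
  out
}

# Hypergeometric upper-tail probability P(X >= x) by direct combinatorial
# summation (log-scale binomial coefficients), independent of phyper().
hyperTailOracle <- function(x, K, N, nSel) {
  hi <- min(K, nSel)
  if (x > hi) return(0)
  i <- max(0, x):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, nSel - i) - lchoose(N, nSel)))
}

# Brute-force row-wise max aggregation of tabular alignment rows.
bruteMaxScores <- function(qid, sid, bit) {
  keys <- unique(paste(qid, sid))
  vapply(keys, function(k) {
    sel <- paste(qid, sid) == k
    max(bit[sel])
  }, numeric(1))
}

# A small random 12-column alignment data.frame.
randomBlastRows <- function(qids, sids, nrows, seed) {
  withr::with_seed(seed, {
    q <- sample(qids, nrows, replace = TRUE)
    s <- sample(sids, nrows, replace = TRUE)
    data.frame(q, s, pid = runif(nrows, 30, 100),
               len = sample(50:500, nrows, TRUE), mm = 0L, go = 0L,
               qs = 1L, qe = 10L, ss = 1L, se = 10L,
               ev = 10^runif(nrows, -50, -1),
               bit = round(runif(nrows, 30, 900), 1))
  })
}

expectedDeltaGrid <- seq(0.70, 0.97, by = 0.03)
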