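# Association statistics: enrichment, FDR, paralogs, pleiotropy, rates,
# biplot and position exports.

test_that("enrichGeneSet reports counts, fold ratio and exact tail p", {
  u <- paste0("g", 1:5791)
  sel <- u[1:47]
  cat100 <- c(u[1:10], u[100:189])  # overlap 10, size 100
  res <- enrichGeneSet(sel, cat100, u)
  expect_equal(res$x, 10)
  expect_equal(res$fold, (10 / 47) / (100 / 5791), tolerance = 1e-12)
  expect_equal(res$fold, 12.3213, tolerance = 1e-4)

  # zero overlap: fold 0, p = P(X >= 0) = 1
  res0 <- enrichGeneSet(u[1:5], u[10:20], u)
  expect_equal(res0$x, 0)
  expect_identical(res0$pOver, 1)

  expect_error(enrichGeneSet("a", "a", character(0)), "empty universe")
  expect_error(enrichGeneSet("zz", u[1:3], u[1:3]), "subset")
})

test_that("enrichment p equals the brute-force hypergeometric tail (N <= 200 spot grid)", {
  withr::with_seed(6, {
    for (rep in 1:300) {
      N <- sample(2:200, 1)
      nSel <- sample(0:N, 1)
      K <- sample(0:N, 1)
      lo <- max(0, K + nSel - N)
      x <- sample(lo:min(K, nSel), 1)
      expect_equal(enrichP(x, K, N, nSel), hyperTailOracle(x, K, N, nSel),
                   tolerance = 1e-12)
    }
  })
})

test_that("fold ratio is invariant to relabeling and common scaling", {
  u <- paste0("g", 1:200)
  sel <- u[1:20]; cat <- u[11:50]
  f1 <- enrichGeneSet(sel, cat, u)$fold
  relabel <- setNames(paste0("x", 1:200), u)
  f2 <- enrichGeneSet(relabel[sel], relabel[cat], relabel[u])$fold
  expect_identical(f1, f2)
  # doubling N, K, nSel, x leaves the fold unchanged
  u2 <- paste0("g", 1:400)
  f3 <- enrichGeneSet(u2[1:40], u2[c(21:100)], u2)$fold
  expect_equal(f3, enrichGeneSet(u[1:20], u[c(11:50)], u)$fold)
})

test_that("adjustFdr is the Benjamini-Hochberg step-up", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFdr(0.2), 0.2)
  expect_identical(adjustFdr(numeric(0)), numeric(0))
  withr::with_seed(2, {
    p <- runif(50)
    a <- adjustFdr(p)
    expect_true(all(a >= p))
    expect_equal(order(a[order(p)]), 1:50)  # order-preserving
  })
  expect_error(adjustFdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("BH controls the discovery rate under the global null", {
  rejected <- total <- 0
  withr::with_seed(123, {
    for (rep in 1:1000) {
      p <- runif(40)
      rejected <- rejected + sum(adjustFdr(p) < 0.05)
      total <- total + 40
    }
  })
  frac <- rejected / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("enrichCategories attaches BH-adjusted p and significance marks", {
  u <- paste0("g", 1:500)
  cats <- list(strong = u[1:30], null1 = u[200:260], null2 = u[300:310])
  sel <- u[1:25]
  res <- enrichCategories(sel, cats, u)
  expect_equal(res$category, names(cats))
  expect_equal(res$pAdjOver, adjustFdr(res$pOver))
  expect_equal(res$marks[1], "***")
  expect_true(all(nchar(res$marks) == vapply(res$pOver, function(p)
    sum(p < c(0.10, 0.05, 0.01)), numeric(1))))
})

test_that("classifyParalogs applies both the e-value and coverage rules", {
  refs <- data.frame(gene = c("gA", "gB", "gC"),
                     selfScore = c(300, 300, 120))
  mk <- function(q, s, len, ev) {
    data.frame(q, s, pid = 50, len = len, mm = 0, go = 0, qs = 1, qe = len,
               ss = 1, se = len, ev = ev, bit = 100)
  }
  rows <- rbind(
    mk("gA", "gB", 160, 1e-12),  # passes: E and coverage 160/300
    mk("gB", "gB", 300, 0),      # self hit: ignored
    mk("gC", "gA", 100, 1e-12)   # coverage 100/120 passes for gC
  )
  fl <- classifyParalogs(rows, refs)
  expect_true(fl[["gA"]])
  expect_false(fl[["gB"]])       # only its self-hit
  expect_true(fl[["gC"]])

  # coverage below half the query length fails even with a strong E
  rows2 <- mk("gA", "gB", 100, 1e-12)  # 100 of 300 = 0.33
  fl2 <- classifyParalogs(rows2, refs)
  expect_false(fl2[["gA"]])
  # weak E fails even with full coverage
  rows3 <- mk("gA", "gB", 300, 1e-8)
  expect_false(classifyParalogs(rows3, refs)[["gA"]])
})

test_that("pleiotropySet applies the ceiling threshold on phenotype counts", {
  sels <- c(
    lapply(1:5, function(i) c("gCommon", paste0("gOnly", i))),
    lapply(6:20, function(i) paste0("gOnly", i))
  )
  ps <- pleiotropySet(sels, fraction = 0.25)
  expect_equal(ps$threshold, 5L)  # ceil(0.25 * 20)
  expect_equal(ps$genes, "gCommon")          # present in 5 of 20
  sels4 <- c(sels[1:4], sels[6:20])           # gCommon now in 4 of 19 -> need 5
  expect_false("gCommon" %in% pleiotropySet(sels4, 0.25)$genes)

  # fraction 0 gives the union, fraction 1 the intersection
  sets <- list(c("a", "b"), c("b", "c"), c("b", "d"))
  expect_equal(pleiotropySet(sets, 0)$genes, c("a", "b", "c", "d"))
  expect_equal(pleiotropySet(sets, 1)$genes, "b")
  expect_equal(pleiotropySet(list(character(0), character(0)), 0.5)$genes,
               character(0))
})

test_that("compareRates is a one-sided Welch t-test on group means", {
  rates <- setNames(c(1, 2, 3, 1, 2, 3), paste0("g", 1:6))
  same <- compareRates(rates, paste0("g", 1:3))
  expect_equal(same$ratio, 1)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 0.5, tolerance = 1e-12)

  # hand Welch arithmetic on a 6-value toy
  a <- c(4, 5, 6); b <- c(1, 2, 3)
  rates2 <- setNames(c(a, b), paste0("g", 1:6))
  res <- compareRates(rates2, paste0("g", 1:3))
  tBrute <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res$t, tBrute, tolerance = 1e-12)
  expect_equal(res$meanSelected, 5)
  expect_equal(res$meanOther, 2)

  # planted shift is detected
  withr::with_seed(77, {
    sel <- rnorm(200, mean = 0.5)
    oth <- rnorm(200, mean = 0)
    rts <- setNames(abs(c(sel, oth)) + 1, paste0("g", 1:400))
    rts[1:200] <- rts[1:200] + 0.5
    out <- compareRates(rts, paste0("g", 1:200))
    expect_lt(out$p, 0.05)
  })
  expect_error(compareRates(rates, "g1"), "at least 2")
})

test_that("biplot coordinates are scores plus bounded correlation loadings", {
  withr::with_seed(50, {
    X <- matrix(rnorm(20 * 15), 20, 15, dimnames = list(NULL, paste0("g", 1:15)))
    y <- as.numeric(X[, 1] + X[, 2]) + 0.2 * rnorm(20)
    fit <- stpls(X, y, ncomp = 3, delta = 0.2)
    bc <- biplotCoords(fit, X)
    expect_equal(dim(bc$scores), c(20L, 2L))
    expect_equal(dim(bc$loadings), c(15L, 2L))
    expect_true(all(abs(bc$loadings) <= 1 + 1e-12))

    # a gene column aligned with the first score direction loads ~(±1, 0)
    t1 <- plsScores(fit)[, 1]
    X2 <- cbind(X, gT = t1)
    fit2 <- stpls(X2, t1, ncomp = 2, delta = 0)
    bc2 <- biplotCoords(fit2, X2)
    expect_gt(abs(bc2$loadings["gT", 1]), 0.95)
    expect_lt(abs(bc2$loadings["gT", 2]), 0.3)

    expect_error(biplotCoords(stpls(X, y, ncomp = 1), X), "fewer components")
  })
})

test_that("chromosomePositions sorts by chromosome then start and flags gaps", {
  ann <- data.frame(
    gene = c("gA", "gB", "gC", "gD"),
    chromosome = c("chrI", "chrI", "chrII", NA),
    strand = c("+", "-", "+", NA),
    start = c(1000, 500, 200, NA),
    end = c(1500, 900, 400, NA)
  )
  out <- chromosomePositions(c("gA", "gB", "gC", "gD"), ann)
  expect_equal(out$gene[1:2], c("gB", "gA"))  # 500 before 1000 on chrI
  expect_equal(out$gene[3], "gC")
  expect_true(out$missing[out$gene == "gD"])
  expect_false(any(out$missing[out$gene != "gD"]))

  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$gene, out$gene)
  expect_equal(back$start, out$start)
})
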