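# Genotype features: best-hit parsing, self scores, normalization,
# filtering and the Jukes-Cantor distance transform.

test_that("parseBlastTabular keeps the per-pair maximum bit-score", {
  hits <- data.frame(q = "g1", s = "YAL001C", pid = 99, len = 100, mm = 1,
                     go = 0, qs = 1, qe = 100, ss = 1, se = 100,
                     ev = 1e-30, bit = c(210.3, 180.1))
  st <- parseBlastTabular(hits)
  expect_equal(nrow(st), 1L)
  expect_equal(st$score, 210.3)
  expect_equal(st$genome, "g1")
  expect_equal(st$gene, "YAL001C")
})

test_that("parseBlastTabular on a generated fixture equals brute-force maxima", {
  rows <- randomBlastRows(paste0("g", 1:3), c("r1", "r2"), 40L, seed = 42)
  st <- parseBlastTabular(rows)
  expect_lte(nrow(st), 6L)
  brute <- bruteMaxScores(rows[[1]], rows[[2]], rows[[12]])
  got <- setNames(st$score, paste(st$genome, st$gene))
  expect_equal(got[names(brute)], setNames(brute, names(brute)))
})

test_that("parseBlastTabular handles empty input, malformed rows and unknown genes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  st <- parseBlastTabular(f)
  expect_equal(nrow(st), 0L)

  writeLines(c(paste(c("g1", "r1", 99, 10, 0, 0, 1, 10, 1, 10, 1e-5, 50),
                     collapse = "\t"),
               "g1\tr1\tbroken"), f)
  expect_error(parseBlastTabular(f), "line 2.*12 columns")

  writeLines(paste(c("g1", "r1", 99, 10, 0, 0, 1, 10, 1, 10, 1e-5, "xx"),
                   collapse = "\t"), f)
  expect_error(parseBlastTabular(f), "line 1.*bit-score")

  rows <- randomBlastRows(c("g1"), c("r1", "rUnknown"), 10L, seed = 1)
  refs <- data.frame(gene = "r1", selfScore = 100)
  expect_error(parseBlastTabular(rows, refs = refs), "unknown gene")
  expect_warning(st <- parseBlastTabular(rows, refs = refs,
                                         unknownGenes = "drop"), "dropping")
  expect_true(all(st$gene == "r1"))
})

test_that("parseBlastTabular maps query ids to genomes by rule", {
  rows <- randomBlastRows(c("s1|c1", "s1|c2", "s2|c1"), "r1", 20L, seed = 3)
  st <- parseBlastTabular(rows, genomeOfQuery = function(q) sub("\\|.*", "", q))
  expect_true(all(st$genome %in% c("s1", "s2")))
  brute <- bruteMaxScores(sub("\\|.*", "", rows[[1]]), rows[[2]], rows[[12]])
  got <- setNames(st$score, paste(st$genome, st$gene))
  expect_equal(got[names(brute)], setNames(brute, names(brute)))
})

test_that("selfScores equal sequence lengths in residues", {
  seqs <- Biostrings::BStringSet(c(
    geneA = paste(rep("M", 300), collapse = ""),
    geneB = "M",
    geneC = "MKTAYIAK"
  ))
  rs <- selfScores(seqs)
  expect_equal(rs$selfScore, c(300, 1, 8))

  withr::with_seed(9, {
    lens <- sample(5:60, 5)
    seqs <- Biostrings::BStringSet(vapply(lens, function(L) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, TRUE),
            collapse = "")
    }, character(1)))
    names(seqs) <- paste0("s", 1:5)
    expect_equal(selfScores(seqs)$selfScore, as.numeric(nchar(as.character(seqs))))
  })
})

test_that("selfScores reads FASTA and rejects degenerate references", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "MKTA", ">g2", "MK"), f)
  rs <- selfScores(f)
  expect_equal(rs$gene, c("g1", "g2"))
  expect_equal(rs$selfScore, c(4, 2))

  dup <- Biostrings::BStringSet(c(a = "MK", a = "MKT"))
  expect_error(selfScores(dup), "duplicated")
  expect_error(selfScores(data.frame(gene = "g", selfScore = 0)), "positive")
})

test_that("normalizeScores clamps to [1/20, 1] and treats absences as the floor", {
  refs <- data.frame(gene = c("r1", "r2", "r3"),
                     selfScore = c(300, 300, 300))
  st <- data.frame(genome = c("g1", "g1", "g2"),
                   gene = c("r1", "r2", "r1"),
                   score = c(150, 3, 700))
  m <- normalizeScores(st, refs)
  expect_equal(m["g1", "r1"], 0.5)        # plain ratio
  expect_equal(m["g1", "r2"], 0.05)       # ratio 0.01 floors at 1/20
  expect_equal(m["g2", "r1"], 1.0)        # bit-score above self-score caps
  expect_equal(m["g1", "r3"], 0.05)       # absent pair scores 0 -> floor
  expect_equal(m["g2", "r3"], 0.05)
  expect_error(normalizeScores(st, data.frame(gene = "r1", selfScore = -1)),
               "positive")
})

test_that("normalized scores stay in [0.05, 1] for arbitrary score tables", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      refs <- data.frame(gene = paste0("r", 1:8),
                         selfScore = runif(8, 1, 500))
      ng <- sample(2:6, 1)
      pairs <- expand.grid(genome = paste0("g", seq_len(ng)),
                           gene = refs$gene, stringsAsFactors = FALSE)
      pairs <- pairs[runif(nrow(pairs)) < 0.7, ]
      pairs$score <- rexp(nrow(pairs), rate = 1 / 200)
      m <- normalizeScores(pairs, refs)
      expect_true(all(m >= 0.05 & m <= 1))
    })
  }
})

test_that("filterReferences drops all-below columns and is idempotent", {
  m <- cbind(a = c(0.40, 0.30, 0.45),    # discarded
             b = c(0.40, 0.60, 0.45),    # retained (one value >= 0.5)
             c = c(0.05, 0.05, 0.05))    # discarded
  rownames(m) <- paste0("g", 1:3)
  res <- filterReferences(m)
  expect_equal(colnames(res$scores), "b")
  expect_equal(sort(res$discarded), c("a", "c"))

  withr::with_seed(5, {
    m2 <- matrix(runif(30, 0.5, 1), 3, 10,
                 dimnames = list(paste0("g", 1:3), paste0("r", 1:10)))
    low <- c(2, 5, 9)
    m2[, low] <- runif(9, 0.05, 0.49)
    res2 <- filterReferences(m2)
    expect_equal(ncol(res2$scores), 7L)
    keepBrute <- which(apply(m2, 2, max) >= 0.5)
    expect_equal(colnames(res2$scores), colnames(m2)[keepBrute])
    twice <- filterReferences(res2$scores)
    expect_identical(twice$scores, res2$scores)
    expect_length(twice$discarded, 0L)
  })
  expect_error(filterReferences(m, threshold = 0), "0, 1")
  expect_error(filterReferences(m, threshold = 1.2), "0, 1")
})

test_that("jcDistance matches the closed form and its boundaries", {
  expect_identical(jcDistance(1.0), 0)
  expect_equal(jcDistance(0.905), -0.95 * log(0.9), tolerance = 1e-12)
  expect_equal(jcDistance(0.905), 0.1000925, tolerance = 1e-6)
  expect_equal(jcDistance(0.05), jcDistanceCap(), tolerance = 1e-12)
  expect_equal(jcDistanceCap(), -0.95 * log(1e-8))
  expect_error(jcDistance(0.02), "clamp")
  expect_error(jcDistance(1.5), "clamp")
})

test_that("jcDistance is strictly decreasing and invertible on its domain", {
  s <- seq(0.0501, 1, length.out = 100)
  d <- jcDistance(s)
  expect_true(all(diff(d) < 0) || all(diff(d) > 0))
  expect_true(all(diff(d) < 0))  # decreasing in s
  sGrid <- seq(1 / 20 + 1e-6, 1, length.out = 50)
  expect_equal(jcScore(jcDistance(sGrid)), sGrid, tolerance = 1e-10)
})

test_that("buildGenotypeMatrix composes normalization, filter and transform", {
  refs <- data.frame(gene = c("r1", "r2", "r3"), selfScore = c(100, 200, 50))
  st <- data.frame(
    genome = rep(c("g1", "g2"), each = 3),
    gene = rep(c("r1", "r2", "r3"), 2),
    score = c(100, 120, 20, 90, 180, 10)
  )
  gm <- buildGenotypeMatrix(st, refs)
  norm <- normalizeScores(st, refs)
  keep <- apply(norm, 2, max) >= 0.5
  manual <- norm[, keep, drop = FALSE]
  manual[] <- jcDistance(as.numeric(manual))
  expect_equal(distMatrix(gm), manual)
  expect_equal(discardedGenes(gm), "r3")  # max 20/50 = 0.4 < 0.5

  # all genomes identical to the reference: all-zero matrix
  stPerfect <- data.frame(genome = rep(c("g1", "g2"), each = 2),
                          gene = rep(c("r1", "r2"), 2),
                          score = c(100, 200, 100, 200))
  gm0 <- buildGenotypeMatrix(stPerfect, refs[1:2, ])
  expect_true(all(distMatrix(gm0) == 0))

  # a gene absent from every genome is filtered out
  refs4 <- rbind(refs[1:2, ], data.frame(gene = "r9", selfScore = 70))
  gm4 <- buildGenotypeMatrix(stPerfect, refs4)
  expect_true("r9" %in% discardedGenes(gm4))
})

test_that("genotype matrix TSV round-trips", {
  refs <- data.frame(gene = c("r1", "r2"), selfScore = c(100, 200))
  st <- data.frame(genome = c("g1", "g2"), gene = c("r1", "r2"),
                   score = c(80, 150))
  gm <- buildGenotypeMatrix(st, refs)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMatrixTsv(distMatrix(gm), f, idColumn = "genome")
  back <- readMatrixTsv(f)
  expect_equal(back, distMatrix(gm), tolerance = 1e-12)
})
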