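# Seeded synthetic data: genotype matrices with block-correlated genes,
# phenotypes from a sparse linear model with known support, score-table
# fixtures whose pipeline output is known by construction, and annotations
# with planted enrichment. Every generator is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators. The defaults
#' mirror the shape of the motivating study at desk scale: n = 36 strains,
#' p genes in correlated blocks (p >> n), a sparse support of s genes with
#' unit effects, and moderate noise.
#'
#' @param n number of strains.
#' @param p number of genes.
#' @param blockSize genes per equicorrelated block.
#' @param rho within-block latent correlation, in \[0, 1).
#' @param s size of the true support.
#' @param effect absolute effect size per support gene.
#' @param sigma phenotype noise standard deviation.
#' @param v number of phenotype columns (for table generation).
#' @param missingRate fraction of phenotype cells set missing.
#' @param nDropped number of planted all-below-threshold genes in the
#'   score-table fixture.
#' @param baseProb baseline category-membership probability for simulated
#'   annotations.
#' @param odds membership odds boost inside the true support (>= 1).
#' @param rateShift multiplicative evolutionary-rate shift for support
#'   genes.
#' @param seed integer seed.
#' @return list of class `simulationConfig`.
#' @export
simulationConfig <- function(n = 36L, p = 1000L, blockSize = 20L, rho = 0.3,
                             s = 10L, effect = 1, sigma = 0.5, v = 1L,
                             missingRate = 0, nDropped = 5L,
                             baseProb = 0.1, odds = 1, rateShift = 1.3,
                             seed = 1L) {
  cfg <- list(n = as.integer(n), p = as.integer(p),
              blockSize = as.integer(blockSize), rho = rho,
              s = as.integer(s), effect = effect, sigma = sigma,
              v = as.integer(v), missingRate = missingRate,
              nDropped = as.integer(nDropped), baseProb = baseProb,
              odds = odds, rateShift = rateShift, seed = as.integer(seed))
  if (cfg$n < 2L || cfg$p < 1L || cfg$blockSize < 1L) {
    stop("counts must be positive (n >= 2)")
  }
  if (cfg$rho < 0 || cfg$rho >= 1) stop("'rho' must lie in [0, 1)")
  if (cfg$s > cfg$p) stop("support size 's' cannot exceed 'p'")
  if (cfg$sigma < 0) stop("'sigma' must be non-negative")
  if (cfg$odds < 1) stop("'odds' must be >= 1")
  class(cfg) <- "simulationConfig"
  cfg
}

strainIds <- function(n) sprintf("strain_%03d", seq_len(n))
geneIds <- function(p) sprintf("gene_%04d", seq_len(p))

# Latent block-equicorrelated standard Gaussians, n x p.
latentBlockGaussian <- function(n, p, blockSize, rho) {
  block <- rep(seq_len(ceiling(p / blockSize)), each = blockSize)[seq_len(p)]
  nBlocks <- max(block)
  common <- matrix(stats::rnorm(n * nBlocks), n, nBlocks)
  noise <- matrix(stats::rnorm(n * p), n, p)
  sqrt(rho) * common[, block, drop = FALSE] + sqrt(1 - rho) * noise
}

#' Simulate a genotype matrix of Jukes-Cantor distances
#'
#' Latent block-equicorrelated Gaussians are squashed monotonically into
#' valid normalized scores in \[0.5, 1\] (so no simulated gene would be
#' caught by the all-below filter) and transformed with [jcDistance()],
#' yielding distances in \[0, dMax\] whose gene-gene correlation follows
#' the block structure.
#'
#' @param cfg a [simulationConfig()].
#' @return A [GenotypeMatrix-class] with synthetic strain/gene labels.
#' @export
simulateGenotypeMatrix <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  withSeed(cfg$seed, {
    z <- latentBlockGaussian(cfg$n, cfg$p, cfg$blockSize, cfg$rho)
    sc <- 1 - 0.5 * stats::pnorm(z)  # monotone: larger z, larger distance
    X <- matrix(jcDistance(as.numeric(sc)), cfg$n, cfg$p,
                dimnames = list(strainIds(cfg$n), geneIds(cfg$p)))
    methods::new("GenotypeMatrix",
      X = X, discarded = character(0), dMax = jcDistanceCap(1e-8),
      lowerBound = 1 / 20, filterThreshold = 0.5)
  })
}

#' Simulate a phenotype from a sparse linear model with known support
#'
#' `y = Z[, support] %*% beta + N(0, sigma^2)`, where Z is the
#' column-standardized genotype matrix (so `effect` is on the
#' per-standardized-gene scale), the support is a random draw of `s`
#' genes, and the signs of the effects are random.
#'
#' @param X a [GenotypeMatrix-class] or plain matrix.
#' @param cfg a [simulationConfig()].
#' @return list with `y` (named numeric) and `truth` (list: `support`,
#'   `beta` named by the support genes, `sigma`).
#' @export
simulatePhenotypes <- function(X, cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  if (methods::is(X, "GenotypeMatrix")) X <- distMatrix(X)
  X <- as.matrix(X)
  Z <- standardizeColumns(X)$x
  withSeed(cfg$seed + 1L, {
    support <- sort(sample.int(ncol(Z), cfg$s))
    beta <- cfg$effect * sample(c(-1, 1), cfg$s, replace = TRUE)
    names(beta) <- colnames(Z)[support]
    y <- as.numeric(Z[, support, drop = FALSE] %*% beta) +
      stats::rnorm(nrow(Z), 0, cfg$sigma)
    names(y) <- rownames(Z)
    list(y = y, truth = list(support = colnames(Z)[support], beta = beta,
                             sigma = cfg$sigma))
  })
}

#' Simulate a phenotype table with known supports and optional missingness
#'
#' Draws `cfg$v` independent phenotype columns with [simulatePhenotypes()]
#' (distinct sub-seeds per column) and, optionally, blanks a random
#' fraction of cells so the imputation step has work to do.
#'
#' @inheritParams simulatePhenotypes
#' @return list with `Y` (n x v matrix, possibly with NAs), `truths`
#'   (per-phenotype truth lists) and `complete` (the matrix before
#'   blanking).
#' @export
simulatePhenotypeTable <- function(X, cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  cols <- lapply(seq_len(cfg$v), function(j) {
    cj <- cfg
    cj$seed <- cfg$seed + 1000L * j
    simulatePhenotypes(X, cj)
  })
  Y <- do.call(cbind, lapply(cols, `[[`, "y"))
  colnames(Y) <- sprintf("pheno_%02d", seq_len(cfg$v))
  complete <- Y
  if (cfg$missingRate > 0) {
    Y <- withSeed(cfg$seed + 99L, {
      holes <- which(stats::runif(length(Y)) < cfg$missingRate)
      # never blank a full row or column
      Ym <- Y
      Ym[holes] <- NA
      bad <- rowSums(!is.na(Ym)) == 0L | FALSE
      Ym[bad, 1L] <- Y[bad, 1L]
      for (j in seq_len(ncol(Ym))) {
        if (all(is.na(Ym[, j]))) Ym[1L, j] <- Y[1L, j]
      }
      Ym
    })
  }
  list(Y = Y, truths = lapply(cols, `[[`, "truth"), complete = complete)
}

#' Simulate a raw score-table fixture with known pipeline output
#'
#' Inverts the feature construction: normalized scores are planted
#' directly (including `nDropped` columns whose scores stay below 0.5 in
#' every strain, which the filter must remove), reference self scores are
#' drawn as integer lengths, and the emitted raw scores are
#' `score = normalized * selfScore`. Cells planted exactly at the 1/20
#' floor are emitted as absent rows (score 0). Running
#' [buildGenotypeMatrix()] on the fixture reproduces `expected`.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `scores` (score-table data.frame), `refs` (reference
#'   set), `expected` (the [GenotypeMatrix-class] the pipeline must
#'   produce), `planted` (the planted normalized-score matrix) and
#'   `droppedGenes`.
#' @export
simulateScoreTable <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  withSeed(cfg$seed + 2L, {
    n <- cfg$n
    pKeep <- cfg$p
    pAll <- pKeep + cfg$nDropped
    genes <- geneIds(pAll)
    strains <- strainIds(n)
    sc <- matrix(0, n, pAll, dimnames = list(strains, genes))
    # surviving genes: scores in [0.55, 1], with a guaranteed max >= 0.5
    sc[, seq_len(pKeep)] <- 0.55 + 0.45 * stats::runif(n * pKeep)
    # sprinkle exact 1.0 (perfect identity) and exact-floor absences
    ones <- which(stats::runif(n * pKeep) < 0.05)
    sc[, seq_len(pKeep)][ones] <- 1
    # planted all-below columns: every score in [0.15, 0.45]
    if (cfg$nDropped > 0L) {
      sc[, pKeep + seq_len(cfg$nDropped)] <-
        0.15 + 0.30 * stats::runif(n * cfg$nDropped)
    }
    # a few absent hits in surviving genes (exactly the floor), but never
    # wiping out a whole column
    floorMask <- matrix(stats::runif(n * pKeep) < 0.03, n, pKeep)
    floorMask[1L, ] <- FALSE
    sc[, seq_len(pKeep)][floorMask] <- 1 / 20

    refs <- data.frame(gene = genes,
                       selfScore = as.numeric(sample(100:1000, pAll,
                                                     replace = TRUE)),
                       stringsAsFactors = FALSE)
    raw <- sweep(sc, 2L, refs$selfScore, "*")
    present <- sc > 1 / 20  # floor cells are encoded by absence
    idx <- which(present, arr.ind = TRUE)
    scores <- data.frame(genome = strains[idx[, 1L]],
                         gene = genes[idx[, 2L]],
                         score = raw[idx],
                         stringsAsFactors = FALSE)
    scores <- scores[order(match(scores$genome, strains), scores$gene), ]
    rownames(scores) <- NULL

    keep <- seq_len(pKeep)
    Xexp <- sc[, keep, drop = FALSE]
    Xexp[] <- jcDistance(as.numeric(sc[, keep, drop = FALSE]))
    expected <- methods::new("GenotypeMatrix",
      X = Xexp, discarded = genes[-keep], dMax = jcDistanceCap(1e-8),
      lowerBound = 1 / 20, filterThreshold = 0.5)
    list(scores = scores, refs = refs, expected = expected, planted = sc,
         droppedGenes = genes[-keep])
  })
}

#' Simulate gene annotations with planted enrichment
#'
#' Category membership is drawn with probability `baseProb` outside the
#' true support and `min(1, odds * baseProb)` inside it; binary variation
#' flags (essential, paralog, frameshift, stop codon, copy number) are
#' drawn the same way (paralog and copy number boosted, the others at
#' baseline); evolutionary rates are log-normal with a multiplicative
#' `rateShift` for support genes, emulating faster evolution of
#' trait-influencing genes.
#'
#' @param genes character vector of gene ids (the universe).
#' @param truth truth list from [simulatePhenotypes()] (uses
#'   `truth$support`), or `NULL` for no planted structure.
#' @param cfg a [simulationConfig()] (uses `baseProb`, `odds`,
#'   `rateShift`, `seed`).
#' @return list with `flags` (data.frame of the five logical columns),
#'   `go` (named list of GO-style term gene sets, the first one planted),
#'   `rates` (named numeric vector).
#' @export
simulateAnnotations <- function(genes, truth, cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  support <- if (is.null(truth)) character(0) else truth$support
  withSeed(cfg$seed + 3L, {
    p <- length(genes)
    inSupp <- genes %in% support
    probs <- ifelse(inSupp, pmin(1, cfg$odds * cfg$baseProb), cfg$baseProb)
    draw <- function(pr) stats::runif(p) < pr
    flags <- data.frame(
      gene = genes,
      essential = draw(cfg$baseProb),
      paralog = draw(probs),
      frameshift = draw(cfg$baseProb),
      stop_codon = draw(cfg$baseProb),
      copy_number = draw(probs),
      stringsAsFactors = FALSE
    )
    go <- list(
      planted_term = genes[draw(probs)],
      null_term_1 = genes[draw(cfg$baseProb)],
      null_term_2 = genes[draw(cfg$baseProb)]
    )
    rates <- stats::rlnorm(p, meanlog = log(0.078), sdlog = 0.4)
    rates[inSupp] <- rates[inSupp] * cfg$rateShift
    names(rates) <- genes
    list(flags = flags, go = go, rates = rates)
  })
}

#' Write a complete simulated fixture directory
#'
#' Generates a score table, reference set, phenotype table (with optional
#' missingness) and annotations under one seed, and writes them as plain
#' TSV/JSON files: `scores.tsv`, `refs.tsv`, `phenotypes.tsv`,
#' `annotations.tsv`, `go.tsv`, `rates.tsv`, `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [simulationConfig()].
#' @return the directory path, invisibly.
#' @export
writeSimulatedFixture <- function(dir, cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- simulateScoreTable(cfg)
  gm <- buildGenotypeMatrix(fix$scores, fix$refs)
  ph <- simulatePhenotypeTable(gm, cfg)
  ann <- simulateAnnotations(colnames(distMatrix(gm)), ph$truths[[1L]], cfg)

  utils::write.table(fix$scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fix$refs, file.path(dir, "refs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writePhenotypes(ph$Y, file.path(dir, "phenotypes.tsv"))
  utils::write.table(ann$flags, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  goLong <- data.frame(
    gene = unlist(ann$go, use.names = FALSE),
    term = rep(names(ann$go), lengths(ann$go)),
    stringsAsFactors = FALSE
  )
  utils::write.table(goLong, file.path(dir, "go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(ann$rates), rate = as.numeric(ann$rates)),
    file.path(dir, "rates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg),
         truths = lapply(ph$truths, function(tr) {
           list(support = tr$support, beta = as.list(tr$beta),
                sigma = tr$sigma)
         }),
         droppedGenes = fix$droppedGenes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
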