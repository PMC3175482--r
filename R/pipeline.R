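# End-to-end pipeline orchestration: genotype features -> imputation ->
# per-phenotype cross-validated ST-PLS -> permutation null (optional) ->
# pleiotropy and enrichment. Configured by a list or YAML file; every
# source of randomness flows from the single configured seed.

#' Read gene annotation inputs
#'
#' `readGeneAnnotation()` reads a TSV with a `gene` column and binary flag
#' columns (e.g. essential, paralog, frameshift, stop_codon, copy_number);
#' `readGoMap()` reads a long-format gene-to-term TSV (columns gene, term)
#' into a named list of gene sets; `readGeneRates()` reads a per-gene
#' evolutionary-rate TSV (columns gene, rate) into a named vector.
#'
#' @param path file path.
#' @return see details.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("annotation table needs a 'gene' column")
  if (anyDuplicated(df$gene)) stop("duplicated gene ids in annotation table")
  for (j in setdiff(names(df), "gene")) {
    if (is.numeric(df[[j]])) df[[j]] <- df[[j]] != 0
    else if (is.character(df[[j]])) df[[j]] <- toupper(df[[j]]) %in%
        c("TRUE", "T", "1", "YES")
  }
  df
}

#' @rdname readGeneAnnotation
#' @export
readGoMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(df))) {
    stop("GO map needs columns 'gene' and 'term'")
  }
  split(df$gene, df$term)
}

#' @rdname readGeneAnnotation
#' @export
readGeneRates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "rate") %in% names(df))) {
    stop("rate table needs columns 'gene' and 'rate'")
  }
  if (any(df$rate < 0, na.rm = TRUE)) stop("rates must be non-negative")
  stats::setNames(df$rate, df$gene)
}

pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full genotype-phenotype mining pipeline
#'
#' Stages: genotype (parse scores and refs, build the distance matrix),
#' impute (KNN imputation of the phenotype table), model (per-phenotype
#' cross-validation, slack-rule selection, refit, d-index), null (optional
#' permutation null per phenotype), association (pleiotropy, enrichment,
#' rate comparison when annotations are given). A JSON summary is written
#' per phenotype, plus TSV exports. Any stage failure aborts with a
#' stage-named error; outputs of completed stages are retained.
#'
#' @param config a list or a YAML/JSON file path with entries:
#'   \describe{
#'     \item{scores, refs, phenotypes}{input paths (scores: BLAST tabular
#'       or 3-column TSV; refs: FASTA or TSV; phenotypes: TSV/CSV).}
#'     \item{annotations, go, rates}{optional annotation paths.}
#'     \item{outDir}{output directory.}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{kGrid, deltaGrid, segmentSize, slackSE, minGenes,
#'       filterThreshold, knnK, nPerm, pleiotropyFraction}{settings,
#'       defaulting to 1:10, the 0.70..0.97 grid, 3, 2, 25, 0.5, 5, 0 and
#'       0.25 respectively.}
#'   }
#' @return invisibly, a list with the per-phenotype choices and summary
#'   paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfgGet <- function(name, default) config[[name]] %||% default
  outDir <- config$outDir %||% stop("config needs an 'outDir'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfgGet("seed", 1L))
  kGrid <- cfgGet("kGrid", 1:10)
  deltaGrid <- cfgGet("deltaGrid", defaultDeltaGrid())
  segmentSize <- cfgGet("segmentSize", 3L)
  slackSE <- cfgGet("slackSE", 2)
  minGenes <- cfgGet("minGenes", 25)
  nPerm <- cfgGet("nPerm", 0L)

  gm <- pipelineStage("genotype", {
    refs <- selfScores(config$refs %||% stop("config needs 'refs'"))
    scoresPath <- config$scores %||% stop("config needs 'scores'")
    first <- utils::read.delim(scoresPath, nrows = 1L, header = TRUE)
    scores <- if (all(c("genome", "gene", "score") %in% names(first))) {
      utils::read.delim(scoresPath, stringsAsFactors = FALSE)
    } else {
      parseBlastTabular(scoresPath, refs = refs)
    }
    gm <- buildGenotypeMatrix(scores, refs,
                              filterThreshold = cfgGet("filterThreshold", 0.5))
    writeMatrixTsv(distMatrix(gm), file.path(outDir, "genotype_matrix.tsv"),
                   idColumn = "genome")
    writeLines(discardedGenes(gm), file.path(outDir, "discarded_genes.txt"))
    gm
  })

  Y <- pipelineStage("impute", {
    Y <- readPhenotypes(config$phenotypes %||% stop("config needs 'phenotypes'"))
    common <- intersect(rownames(Y), rownames(distMatrix(gm)))
    if (length(common) < nrow(distMatrix(gm))) {
      stop("phenotype table lacks strains present in the genotype matrix")
    }
    Y <- Y[rownames(distMatrix(gm)), , drop = FALSE]
    Y <- knnImpute(Y, k = cfgGet("knnK", 5L))
    writePhenotypes(Y, file.path(outDir, "phenotypes_imputed.tsv"))
    Y
  })

  X <- distMatrix(gm)
  phenoSeeds <- deriveSeeds(seed, ncol(Y) * 2L)
  choices <- vector("list", ncol(Y))
  names(choices) <- colnames(Y)
  summaries <- character(ncol(Y))
  selections <- vector("list", ncol(Y))
  names(selections) <- colnames(Y)

  for (j in seq_len(ncol(Y))) {
    label <- colnames(Y)[j]
    choices[[j]] <- pipelineStage(paste0("model:", label), {
      cv <- crossValidate(X, Y[, j], kGrid = kGrid, deltaGrid = deltaGrid,
                          segmentSize = segmentSize, seed = phenoSeeds[j])
      suppressWarnings(selectModel(cv, slackSE = slackSE,
                                   minGenes = minGenes))
    })
    ch <- choices[[j]]
    selections[[j]] <- selectedGenes(ch)
    nullDf <- NULL
    if (nPerm > 0L) {
      nullDf <- pipelineStage(paste0("null:", label), {
        permutationNull(X, Y[, j], nPerm = nPerm,
                        seed = phenoSeeds[ncol(Y) + j], kGrid = kGrid,
                        deltaGrid = deltaGrid, segmentSize = segmentSize,
                        slackSE = slackSE, minGenes = minGenes)
      })
    }
    summaries[j] <- file.path(outDir, sprintf("summary_%s.json", label))
    jsonlite::write_json(list(
      phenotype = label,
      k = ch@k, delta = ch@delta,
      cvrmse = ch@cvrmse, slackBound = ch@slackBound,
      dIndex = ch@dIndex,
      nSelected = length(selectedGenes(ch)),
      selected = selectedGenes(ch),
      minGenesRelaxed = ch@relaxed,
      seed = phenoSeeds[j],
      null = if (is.null(nullDf)) NULL else list(
        dIndex = nullDf$dIndex, nSelected = nullDf$nSelected)
    ), summaries[j], auto_unbox = TRUE, digits = NA, null = "null")
  }

  assoc <- pipelineStage("association", {
    pleio <- pleiotropySet(selections,
                           fraction = cfgGet("pleiotropyFraction", 0.25))
    utils::write.table(
      data.frame(gene = names(pleio$counts),
                 count = as.integer(pleio$counts),
                 pleiotropic = names(pleio$counts) %in% pleio$genes),
      file.path(outDir, "pleiotropy.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    out <- list(pleiotropy = pleio)
    universe <- colnames(X)
    if (!is.null(config$annotations) || !is.null(config$go)) {
      categories <- list()
      if (!is.null(config$annotations)) {
        fl <- readGeneAnnotation(config$annotations)
        for (col in setdiff(names(fl), "gene")) {
          categories[[col]] <- intersect(fl$gene[fl[[col]]], universe)
        }
      }
      if (!is.null(config$go)) {
        go <- readGoMap(config$go)
        for (tm in names(go)) {
          categories[[tm]] <- intersect(go[[tm]], universe)
        }
      }
      enr <- lapply(selections, function(sel) {
        enrichCategories(intersect(sel, universe), categories, universe)
      })
      enrAll <- do.call(rbind, Map(function(df, ph) {
        cbind(phenotype = ph, df)
      }, enr, names(enr)))
      utils::write.table(enrAll, file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$enrichment <- enrAll
    }
    if (!is.null(config$rates)) {
      rates <- readGeneRates(config$rates)
      rates <- rates[names(rates) %in% universe]
      overall <- unique(unlist(selections))
      out$rateComparison <- tryCatch(compareRates(rates, overall),
                                     error = function(e) NULL)
      if (!is.null(out$rateComparison)) {
        jsonlite::write_json(out$rateComparison,
                             file.path(outDir, "rate_comparison.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    out
  })

  jsonlite::write_json(
    list(seed = seed, phenotypes = colnames(Y),
         settings = list(kGrid = kGrid, deltaGrid = deltaGrid,
                         segmentSize = segmentSize, slackSE = slackSE,
                         minGenes = minGenes, nPerm = nPerm),
         version = as.character(utils::packageVersion("stpls"))),
    file.path(outDir, "run.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(choices = choices, selections = selections,
                 association = assoc, summaries = summaries,
                 outDir = outDir))
}
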