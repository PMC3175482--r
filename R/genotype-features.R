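# Genotype features: from pairwise-alignment best-hit scores to a matrix of
# approximate evolutionary distances.
#
# For each genome g and reference gene r the best alignment bit-score
# S(g; r) is normalized by the gene's self-alignment score S(r; r) under
# unit match scoring (which equals the sequence length in residues),
# clamped to [1/20, 1]. Genes whose normalized score is below 0.5 in every
# genome carry no signal and are discarded. Surviving scores are mapped to
# approximate evolutionary distances with the 20-state (amino-acid)
# Jukes-Cantor model, which saturates exactly at the 1/20 floor.

#' Parse tabular pairwise-alignment output into a best-hit score table
#'
#' Reads the 12-column BLAST tabular dialect (outfmt 6: query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit-score) and keeps, for every
#' (genome, gene) pair, the maximum bit-score over all its HSPs. Subject
#' ids are reference gene ids; query ids are mapped to genome ids by
#' `genomeOfQuery` (by default the query id is the genome id).
#'
#' @param x path to a tabular file, or a data.frame whose first, second and
#'   twelfth columns are query id, subject id and bit-score.
#' @param genomeOfQuery `NULL` (identity), a function mapping query ids to
#'   genome ids, or a named character vector used as a lookup table.
#' @param refs optional reference set (see [selfScores()]); when given,
#'   hits against unknown gene ids are handled per `unknownGenes`.
#' @param unknownGenes `"error"` (default) or `"drop"` (drop with a warning).
#' @return A score table: data.frame with columns `genome`, `gene`, `score`,
#'   one row per observed (genome, gene) pair. Pairs with no hits are absent
#'   and are treated as score 0 downstream.
#' @export
#' @examples
#' hits <- data.frame(q = "s1", s = "g1", pid = 100, len = 10, mm = 0,
#'                    go = 0, qs = 1, qe = 10, ss = 1, se = 10,
#'                    ev = 1e-5, bit = c(210.3, 180.1))
#' parseBlastTabular(hits)
parseBlastTabular <- function(x, genomeOfQuery = NULL, refs = NULL,
                              unknownGenes = c("error", "drop")) {
  unknownGenes <- match.arg(unknownGenes)
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
    lineNo <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L)) {
      bad <- which(nf != 12L)[1L]
      stop(sprintf(
        "malformed alignment row at line %d: expected 12 columns, found %d",
        lineNo[bad], nf[bad]))
    }
    qid <- vapply(fields, `[[`, "", 1L)
    sid <- vapply(fields, `[[`, "", 2L)
    bitRaw <- vapply(fields, `[[`, "", 12L)
    bit <- suppressWarnings(as.numeric(bitRaw))
    if (anyNA(bit)) {
      bad <- which(is.na(bit))[1L]
      stop(sprintf("malformed alignment row at line %d: non-numeric bit-score '%s'",
                   lineNo[bad], bitRaw[bad]))
    }
  } else if (is.data.frame(x)) {
    if (ncol(x) < 12L) stop("alignment data.frame must have 12 columns")
    qid <- as.character(x[[1L]])
    sid <- as.character(x[[2L]])
    bit <- x[[12L]]
    if (!is.numeric(bit)) {
      bit <- suppressWarnings(as.numeric(bit))
      if (anyNA(bit)) {
        stop(sprintf("malformed alignment row at line %d: non-numeric bit-score",
                     which(is.na(bit))[1L]))
      }
    }
  } else {
    stop("'x' must be a file path or a data.frame")
  }

  genome <- if (is.null(genomeOfQuery)) {
    qid
  } else if (is.function(genomeOfQuery)) {
    as.character(genomeOfQuery(qid))
  } else if (is.character(genomeOfQuery)) {
    unknown <- setdiff(unique(qid), names(genomeOfQuery))
    if (length(unknown)) {
      stop("no genome label for query id(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    unname(genomeOfQuery[qid])
  } else {
    stop("'genomeOfQuery' must be NULL, a function or a named character vector")
  }

  if (!is.null(refs)) {
    refs <- asReferenceSet(refs)
    foreign <- !(sid %in% refs$gene)
    if (any(foreign)) {
      if (unknownGenes == "error") {
        stop("hits against unknown gene id(s): ",
             paste(utils::head(unique(sid[foreign]), 5L), collapse = ", "))
      }
      warning(sprintf("dropping %d hit(s) against unknown gene ids",
                      sum(foreign)))
      genome <- genome[!foreign]; sid <- sid[!foreign]; bit <- bit[!foreign]
    }
  }

  if (!length(bit)) {
    return(data.frame(genome = character(0), gene = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(genome, sid, sep = "\r")
  best <- tapply(bit, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(
    genome = vapply(parts, `[[`, "", 1L),
    gene = vapply(parts, `[[`, "", 2L),
    score = as.numeric(best),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(match(out$genome, unique(genome)), out$gene), , drop = FALSE]
}

# Validate / coerce a reference set: data.frame with columns gene, selfScore
# and optionally chromosome, strand, start, end.
asReferenceSet <- function(refs) {
  if (!is.data.frame(refs)) stop("reference set must be a data.frame")
  nm <- names(refs)
  if (!("gene" %in% nm)) {
    gidCol <- intersect(c("gene_id", "id"), nm)
    if (length(gidCol)) names(refs)[nm == gidCol[1L]] <- "gene"
    else stop("reference set needs a 'gene' column")
  }
  nm <- names(refs)
  if (!("selfScore" %in% nm)) {
    ssCol <- intersect(c("self_score", "selfscore", "length"), nm)
    if (length(ssCol)) names(refs)[nm == ssCol[1L]] <- "selfScore"
    else stop("reference set needs a 'selfScore' column")
  }
  refs$gene <- as.character(refs$gene)
  if (anyDuplicated(refs$gene)) {
    stop("duplicated reference gene id(s): ",
         paste(utils::head(unique(refs$gene[duplicated(refs$gene)]), 5L),
               collapse = ", "))
  }
  if (any(!is.finite(refs$selfScore)) || any(refs$selfScore <= 0)) {
    stop("self-alignment scores must be positive")
  }
  if (all(c("start", "end") %in% names(refs))) {
    ok <- is.na(refs$start) | is.na(refs$end) | refs$start <= refs$end
    if (!all(ok)) stop("reference coordinates must satisfy start <= end")
  }
  refs
}

#' Self-alignment scores of the reference genes
#'
#' Under unit match scoring, the maximum self-alignment score of a sequence
#' equals its length in residues; these scores are the normalization
#' denominators of the genotype features.
#'
#' @param x an `XStringSet` of reference sequences, a FASTA path, a TSV
#'   path (columns gene id and self-score), or a data.frame with columns
#'   `gene` and `selfScore`.
#' @return Reference set data.frame with columns `gene` and `selfScore`
#'   (plus any coordinate columns carried through).
#' @export
selfScores <- function(x) {
  if (methods::is(x, "XStringSet")) {
    ids <- sub("\\s.*$", "", names(x) %||% stop("sequences must be named"))
    len <- Biostrings::width(x)
  } else if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.(fa|fasta|faa|fna)(\\.gz)?$", x, ignore.case = TRUE)) {
      return(selfScores(Biostrings::readBStringSet(x)))
    }
    tab <- utils::read.delim(x, stringsAsFactors = FALSE)
    return(asReferenceSet(tab))
  } else if (is.data.frame(x)) {
    return(asReferenceSet(x))
  } else {
    stop("'x' must be sequences, a path, or a data.frame")
  }
  if (anyDuplicated(ids)) {
    stop("duplicated sequence id(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  if (any(len == 0L)) {
    stop("zero-length sequence(s): ",
         paste(utils::head(ids[len == 0L], 5L), collapse = ", "))
  }
  data.frame(gene = ids, selfScore = as.numeric(len), stringsAsFactors = FALSE)
}

#' Normalize best-hit scores by self-alignment scores
#'
#' Each score S(g; r) is divided by the gene's self score S(r; r) and the
#' ratio is clamped to \[`lowerBound`, 1\]. Pairs absent from the score
#' table are treated as score 0 and therefore normalize to the floor
#' (absence of detectable homology is maximal divergence). Ratios above 1
#' can occur because bit-scores and unit-match self scores live on
#' different scales; they are capped at 1.
#'
#' @param scores score table from [parseBlastTabular()] (columns genome,
#'   gene, score).
#' @param refs reference set from [selfScores()].
#' @param lowerBound the normalization floor, default 1/20 (the saturation
#'   point of the 20-state Jukes-Cantor transform).
#' @return n x p numeric matrix of normalized scores in \[lowerBound, 1\],
#'   with genome rownames (input order) and one column per reference gene.
#' @export
normalizeScores <- function(scores, refs, lowerBound = 1 / 20) {
  refs <- asReferenceSet(refs)
  if (!is.data.frame(scores) ||
      !all(c("genome", "gene", "score") %in% names(scores))) {
    stop("'scores' must have columns genome, gene, score")
  }
  if (any(scores$score < 0)) stop("scores must be non-negative")
  if (anyDuplicated(scores[c("genome", "gene")])) {
    stop("more than one score for some (genome, gene) pair")
  }
  missingGenes <- setdiff(scores$gene, refs$gene)
  if (length(missingGenes)) {
    stop("score table references unknown gene id(s): ",
         paste(utils::head(missingGenes, 5L), collapse = ", "))
  }
  genomes <- unique(scores$genome)
  m <- matrix(0, nrow = length(genomes), ncol = nrow(refs),
              dimnames = list(genomes, refs$gene))
  m[cbind(match(scores$genome, genomes), match(scores$gene, refs$gene))] <-
    scores$score
  m <- sweep(m, 2L, refs$selfScore, "/")
  pmin(pmax(m, lowerBound), 1)
}

#' Discard reference genes with no clear similarity in any genome
#'
#' A gene column is dropped when its normalized score is below `threshold`
#' in every genome: such genes contribute noise rather than information.
#'
#' @param m normalized-score matrix from [normalizeScores()].
#' @param threshold in (0, 1\]; default 0.5.
#' @return list with `scores` (the surviving columns, order preserved) and
#'   `discarded` (character vector of dropped gene ids).
#' @export
filterReferences <- function(m, threshold = 0.5) {
  assertMatrixLike(m, "m")
  if (!nrow(m) || !ncol(m)) stop("'m' must be non-empty")
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must lie in (0, 1]")
  }
  keep <- apply(m, 2L, max) >= threshold
  list(scores = m[, keep, drop = FALSE],
       discarded = colnames(m)[!keep])
}

#' Jukes-Cantor distance of a normalized score
#'
#' The 20-state (amino-acid) Jukes-Cantor transform
#' `d = -(19/20) * log((20 * s - 1) / 19)` maps a normalized score
#' s in \[1/20, 1\] to an approximate evolutionary distance. The closed
#' form diverges at s = 1/20, so the logarithm's argument is floored at
#' `eps`, giving the finite cap `dMax = -(19/20) * log(eps)`. The distance
#' is 0 exactly when s = 1 (the gene is found at 100% identity).
#'
#' @param s numeric vector of normalized scores in \[0.05, 1\].
#' @param eps floor for the log argument; default 1e-8.
#' @return distances in \[0, dMax\].
#' @seealso [jcScore()] for the inverse map, [jcDistanceCap()] for the cap.
#' @export
#' @examples
#' jcDistance(1)            # 0
#' jcDistance(0.905)        # -0.95 * log(0.9)
jcDistance <- function(s, eps = 1e-8) {
  if (!is.numeric(s)) stop("'s' must be numeric")
  tol <- 1e-12
  bad <- !is.finite(s) | s < 1 / 20 - tol | s > 1 + tol
  if (any(bad)) {
    stop(sprintf(
      "normalized scores must lie in [0.05, 1] (got %s); clamp them first",
      paste(utils::head(signif(s[bad], 6), 5L), collapse = ", ")))
  }
  -(19 / 20) * log(pmax((20 * s - 1) / 19, eps)) + 0
}

#' @rdname jcDistance
#' @param d numeric vector of distances.
#' @details `jcScore()` is the inverse transform
#'   `s = (1 + 19 * exp(-d / 0.95)) / 20`, useful for round-trip checks and
#'   simulation.
#' @export
jcScore <- function(d) (1 + 19 * exp(-d / 0.95)) / 20

#' @rdname jcDistance
#' @export
jcDistanceCap <- function(eps = 1e-8) -(19 / 20) * log(eps)

#' Build the genotype matrix X from best-hit scores
#'
#' Composition of [normalizeScores()], [filterReferences()] and an
#' elementwise [jcDistance()]: the resulting matrix has one row per genome
#' and one column per reference gene surviving the filter, holding
#' approximate evolutionary distances from the reference genome.
#'
#' @inheritParams normalizeScores
#' @param filterThreshold the all-below filter threshold; default 0.5.
#' @param eps log-argument floor of the distance transform.
#' @param genomeOrder `"input"` (order of first appearance in the score
#'   table) or `"sorted"`.
#' @return A [GenotypeMatrix-class].
#' @export
buildGenotypeMatrix <- function(scores, refs, filterThreshold = 0.5,
                                lowerBound = 1 / 20, eps = 1e-8,
                                genomeOrder = c("input", "sorted")) {
  genomeOrder <- match.arg(genomeOrder)
  m <- normalizeScores(scores, refs, lowerBound = lowerBound)
  if (nrow(m) < 2L) stop("at least 2 genomes are required")
  if (genomeOrder == "sorted") m <- m[order(rownames(m)), , drop = FALSE]
  filt <- filterReferences(m, threshold = filterThreshold)
  X <- filt$scores
  X[] <- jcDistance(as.numeric(filt$scores), eps = eps)
  methods::new("GenotypeMatrix",
    X = X, discarded = filt$discarded, dMax = jcDistanceCap(eps),
    lowerBound = lowerBound, filterThreshold = filterThreshold)
}

#' Read and write labelled matrices as TSV
#'
#' TSV layout: header row of gene ids with a leading id column name, one
#' row per genome/strain. Used for genotype and normalized-score matrices
#' and for phenotype tables.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @param idColumn name for the leading id column.
#' @return `readMatrixTsv` returns the matrix; `writeMatrixTsv` its path,
#'   invisibly.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
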