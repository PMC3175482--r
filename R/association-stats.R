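# Post-processing of selected gene sets: paralog classification, category
# and GO enrichment (one-sided Fisher exact tests with BH adjustment and
# significance marks), pleiotropy summaries, evolutionary-rate comparison,
# and biplot / chromosome-position exports.

#' Hypergeometric tail probability used by the enrichment test
#'
#' One-sided (enrichment-direction) Fisher exact p-value for a 2x2 table
#' with `x` selected genes in the category, `nSel` selected genes, `K`
#' category genes and universe size `N`: the probability of observing at
#' least `x` category genes in a draw of `nSel` from the universe,
#' `P(X >= x)` under the hypergeometric distribution. Vectorized over all
#' arguments.
#'
#' @param x overlap count.
#' @param K category size.
#' @param N universe size.
#' @param nSel selected-set size.
#' @return p-values in (0, 1\].
#' @export
enrichP <- function(x, K, N, nSel) {
  stats::phyper(x - 1, K, N - K, nSel, lower.tail = FALSE)
}

#' Enrichment of a gene category in a selected gene set
#'
#' One-sided Fisher exact test (enrichment direction) of the 2x2 table
#' `[(x, nSel - x), (K - x, N - nSel - K + x)]`, with the complementary
#' depletion-direction p-value also reported, plus the fold ratio
#' `(x / nSel) / (K / N)` (0 when either set is empty).
#'
#' @param selected character vector of selected genes (subset of
#'   `universe`).
#' @param category character vector of category member genes (subset of
#'   `universe`).
#' @param universe character vector, the reference gene set.
#' @param label optional category label.
#' @return one-row data.frame with columns `category`, `N`, `nSel`, `K`,
#'   `x`, `fold`, `pOver`, `pUnder`.
#' @export
#' @examples
#' u <- paste0("g", 1:200)
#' enrichGeneSet(u[1:20], u[10:40], u)
enrichGeneSet <- function(selected, category, universe, label = NA_character_) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  selected <- unique(as.character(selected))
  category <- unique(as.character(category))
  if (length(setdiff(selected, universe))) {
    stop("'selected' must be a subset of 'universe'")
  }
  if (length(setdiff(category, universe))) {
    stop("'category' must be a subset of 'universe'")
  }
  N <- length(universe)
  nSel <- length(selected)
  K <- length(category)
  x <- length(intersect(selected, category))
  fold <- if (nSel * K == 0) 0 else (x / nSel) / (K / N)
  data.frame(
    category = label, N = N, nSel = nSel, K = K, x = x, fold = fold,
    pOver = enrichP(x, K, N, nSel),
    pUnder = stats::phyper(x, K, N - K, nSel),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value list (monotone,
#' capped at 1); a thin wrapper around [stats::p.adjust()] kept for a
#' uniform surface.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return adjusted p-values.
#' @export
adjustFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Significance marks at 10%/5%/1%.
sigMarks <- function(p, symbol = "*") {
  vapply(p, function(pi) {
    strrep(symbol, sum(pi < c(0.10, 0.05, 0.01)))
  }, character(1))
}

#' Enrichment table over many categories
#'
#' Runs [enrichGeneSet()] for every category, BH-adjusts the
#' enrichment-direction p-values across categories, and attaches the
#' significance marks used in the result tables: `*`, `**`, `***` for raw
#' p below 10%, 5%, 1%, and the same thresholds with bullet marks for the
#' adjusted p.
#'
#' @inheritParams enrichGeneSet
#' @param categories named list of gene sets.
#' @return data.frame with one row per category: counts, fold ratio, raw
#'   and adjusted p-values, and mark columns `marks` / `adjMarks`.
#' @export
enrichCategories <- function(selected, categories, universe) {
  if (!length(categories)) {
    stop("'categories' must be a non-empty named list")
  }
  labels <- names(categories) %||% as.character(seq_along(categories))
  rows <- lapply(seq_along(categories), function(i) {
    enrichGeneSet(selected, categories[[i]], universe, label = labels[i])
  })
  out <- do.call(rbind, rows)
  out$pAdjOver <- adjustFdr(out$pOver)
  out$marks <- sigMarks(out$pOver, "*")
  out$adjMarks <- sigMarks(out$pAdjOver, "•")
  rownames(out) <- NULL
  out
}

#' Classify reference genes as paralogs from within-genome alignment hits
#'
#' A gene is flagged as having a paralog when it has a non-self protein
#' alignment hit among the other reference genes with e-value below
#' `eMax` covering at least `minCov` of its length. Query lengths come
#' from the reference self scores (length in residues under unit match
#' scoring).
#'
#' @param blastRows 12-column tabular alignment rows among the reference
#'   genes (path or data.frame, as in [parseBlastTabular()]).
#' @param refs reference set with `gene` and `selfScore` columns.
#' @param eMax e-value threshold; default 1e-10.
#' @param minCov minimum fraction of the query length aligned; default 0.5.
#' @return named logical vector over all reference genes.
#' @export
classifyParalogs <- function(blastRows, refs, eMax = 1e-10, minCov = 0.5) {
  refs <- asReferenceSet(refs)
  if (is.character(blastRows) && length(blastRows) == 1L) {
    blastRows <- utils::read.delim(blastRows, header = FALSE,
                                   stringsAsFactors = FALSE)
  }
  if (!is.data.frame(blastRows) || ncol(blastRows) < 12L) {
    stop("'blastRows' must be 12-column tabular alignment rows")
  }
  qid <- as.character(blastRows[[1L]])
  sid <- as.character(blastRows[[2L]])
  alnLen <- suppressWarnings(as.numeric(blastRows[[4L]]))
  eval <- suppressWarnings(as.numeric(blastRows[[11L]]))
  if (anyNA(alnLen) || anyNA(eval)) {
    stop("malformed alignment rows: non-numeric length or e-value")
  }
  unknown <- setdiff(unique(qid), refs$gene)
  if (length(unknown)) {
    stop("query id(s) not in the reference set: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  qlen <- refs$selfScore[match(qid, refs$gene)]
  hit <- qid != sid & eval < eMax & alnLen >= minCov * qlen
  flags <- stats::setNames(rep(FALSE, nrow(refs)), refs$gene)
  flags[unique(qid[hit])] <- TRUE
  flags
}

#' Genes selected across many phenotypes (pleiotropy)
#'
#' Counts, for every gene, the phenotypes in whose selected set it
#' appears, and returns the genes present in at least
#' `ceiling(fraction * #phenotypes)` of them.
#'
#' @param selections list of per-phenotype selected gene sets.
#' @param fraction minimum fraction of phenotypes; default 0.25.
#' @return list with `genes` (the pleiotropic set), `counts` (named
#'   integer vector over all ever-selected genes) and `threshold` (the
#'   count cutoff used).
#' @export
pleiotropySet <- function(selections, fraction = 0.25) {
  if (!length(selections)) stop("at least one phenotype selection is required")
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  counted <- table(unlist(lapply(selections, unique)))
  counts <- stats::setNames(as.integer(counted),
                            as.character(names(counted) %||% character(0)))
  threshold <- as.integer(ceiling(fraction * length(selections)))
  genes <- names(counts)[counts >= threshold]
  list(genes = sort(genes), counts = counts, threshold = threshold)
}

#' Compare evolutionary rates of selected vs other genes
#'
#' Welch (unequal-variance) two-sample t-test, one-sided in the direction
#' "selected genes evolve faster", on per-gene evolutionary rates (e.g.
#' non-synonymous / synonymous frequency ratios).
#'
#' @param rates named numeric vector of per-gene rates (>= 0).
#' @param selected character vector of selected genes; all other named
#'   rates form the comparison group.
#' @return list with `meanSelected`, `meanOther`, `ratio`, `t`, `p`
#'   (one-sided), `nSelected`, `nOther`.
#' @export
compareRates <- function(rates, selected) {
  if (is.null(names(rates))) stop("'rates' must be a named vector")
  rates <- rates[is.finite(rates)]
  inSel <- names(rates) %in% selected
  a <- rates[inSel]
  b <- rates[!inSel]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 genes with rates")
  }
  tt <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  list(
    meanSelected = mean(a), meanOther = mean(b),
    ratio = mean(a) / mean(b),
    t = unname(tt$statistic), p = tt$p.value,
    nSelected = length(a), nOther = length(b)
  )
}

#' Correlation-biplot coordinates over two PLS components
#'
#' Sample scores are the chosen columns of the model's score matrix T;
#' gene coordinates are correlation loadings, the Pearson correlation of
#' every standardized gene column with each score column (bounded in
#' \[-1, 1\]). Constant gene columns get loading 0 with a warning.
#'
#' @param model an [STPLSModel-class] with at least `max(components)`
#'   components.
#' @param X the genotype matrix on the original scale (it is standardized
#'   internally with the model's training parameters); a
#'   [GenotypeMatrix-class] or plain matrix.
#' @param components two component indices; default c(1, 2).
#' @return list with `scores` (n x 2) and `loadings` (p x 2).
#' @export
biplotCoords <- function(model, X, components = c(1, 2)) {
  stopifnot(methods::is(model, "STPLSModel"))
  components <- as.integer(components)
  if (length(components) != 2L || any(components < 1L)) {
    stop("'components' must be two positive indices")
  }
  if (model@ncomp < max(components)) {
    stop("model has fewer components than requested")
  }
  if (methods::is(X, "GenotypeMatrix")) X <- distMatrix(X)
  X <- as.matrix(X)
  genes <- names(model@coefficients)
  X <- X[, genes, drop = FALSE]
  Z <- sweep(sweep(X, 2L, model@xCenter, "-"), 2L, model@xScale, "/")
  Tm <- model@scores[, components, drop = FALSE]
  sdZ <- apply(Z, 2L, stats::sd)
  loadings <- matrix(0, ncol(Z), 2L,
                     dimnames = list(genes, colnames(Tm)))
  ok <- sdZ > 0
  if (any(!ok)) {
    warning(sprintf("%d constant gene column(s): loadings set to 0",
                    sum(!ok)))
  }
  if (any(ok)) {
    loadings[ok, ] <- stats::cor(Z[, ok, drop = FALSE], Tm)
  }
  list(scores = Tm, loadings = loadings)
}

#' Chromosome positions of selected genes
#'
#' Extracts (gene, chromosome, strand, start, end) rows for the selected
#' genes, sorted by chromosome then start, for external plotting. Genes
#' without coordinates are flagged, not dropped.
#'
#' @param selected character vector of gene ids.
#' @param ann data.frame with columns `gene`, `chromosome`, `strand`,
#'   `start`, `end`.
#' @return data.frame with the coordinate columns plus a logical
#'   `missing` flag; flagged rows sort last.
#' @export
chromosomePositions <- function(selected, ann) {
  need <- c("gene", "chromosome", "strand", "start", "end")
  if (!is.data.frame(ann) || !all(need %in% names(ann))) {
    stop("'ann' must have columns gene, chromosome, strand, start, end")
  }
  idx <- match(selected, ann$gene)
  out <- data.frame(
    gene = as.character(selected),
    chromosome = as.character(ann$chromosome[idx]),
    strand = as.character(ann$strand[idx]),
    start = ann$start[idx],
    end = ann$end[idx],
    stringsAsFactors = FALSE
  )
  out$missing <- is.na(idx) | is.na(out$chromosome) | is.na(out$start)
  ord <- order(out$missing, out$chromosome, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
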