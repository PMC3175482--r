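# Phenotype preparation: reading, K-nearest-neighbour imputation and
# column standardization of the strain x phenotype table.

#' Read and write a phenotype table
#'
#' TSV or CSV with a header row; the first column holds strain ids, the
#' remaining columns real-valued phenotype measures. Missing values are
#' encoded as empty fields or `NA`.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @return numeric matrix with strain rownames and phenotype colnames.
#' @export
readPhenotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (anyDuplicated(df[[1L]])) stop("duplicated strain ids in phenotype table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("duplicated phenotype labels")
  m
}

#' @rdname readPhenotypes
#' @param m phenotype matrix.
#' @export
writePhenotypes <- function(m, path) {
  writeMatrixTsv(m, path, idColumn = "strain")
}

#' K-nearest-neighbour imputation of missing phenotype values
#'
#' Each missing cell (i, j) is replaced by the unweighted mean of column j
#' among the `k` rows nearest to row i in overall phenotype pattern.
#' Distances are Euclidean (root mean square over the columns observed in
#' both rows) on per-column standardized values, and rows missing column j
#' are excluded from the neighbour pool. Observed cells are never changed,
#' and imputed cells never feed back into the distances.
#'
#' @param m numeric matrix with possible `NA`s; every row must have at
#'   least one observed value and every column at least `k`.
#' @param k number of neighbours; default 5.
#' @return the matrix with all `NA`s filled in.
#' @export
knnImpute <- function(m, k = 5L) {
  assertMatrixLike(m, "m")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be a positive integer")
  miss <- is.na(m)
  if (!any(miss)) return(m)
  obsPerCol <- colSums(!miss)
  if (any(obsPerCol == 0L)) {
    stop("column(s) entirely missing: ",
         paste(colnames(m)[obsPerCol == 0L], collapse = ", "))
  }
  if (any(obsPerCol < k)) {
    stop(sprintf("column(s) with fewer than k = %d observed values: %s", k,
                 paste(colnames(m)[obsPerCol < k], collapse = ", ")))
  }
  if (any(rowSums(!miss) == 0L)) stop("row(s) entirely missing")

  ctr <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(m, 2L, ctr, "-"), 2L, sdv, "/")

  out <- m
  rid <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cid <- colnames(m) %||% as.character(seq_len(ncol(m)))
  for (i in which(rowSums(miss) > 0L)) {
    for (j in which(miss[i, ])) {
      pool <- which(!miss[, j] & seq_len(nrow(m)) != i)
      d <- vapply(pool, function(r) {
        shared <- !miss[i, ] & !miss[r, ]
        if (!any(shared)) return(NA_real_)
        sqrt(mean((z[i, shared] - z[r, shared])^2))
      }, numeric(1))
      pool <- pool[is.finite(d)]
      d <- d[is.finite(d)]
      if (length(pool) < k) {
        stop(sprintf(
          "cell (%s, %s): only %d usable neighbour(s), need k = %d",
          rid[i], cid[j], length(pool), k))
      }
      nn <- pool[order(d)][seq_len(k)]
      out[i, j] <- mean(m[nn, j])
    }
  }
  out
}

#' Centre and standardize matrix columns
#'
#' Subtracts the column mean and divides by the sample (n - 1) standard
#' deviation, the convention used throughout the package. The returned
#' parameters can be re-applied to held-out rows so that test samples are
#' standardized with training-set statistics only.
#'
#' @param m numeric matrix; every column must have positive variance.
#' @return list with `x` (standardized matrix) and `params` (list with
#'   named `center` and `scale` vectors).
#' @export
standardizeColumns <- function(m) {
  assertMatrixLike(m, "m")
  ctr <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance column(s): ",
         paste((colnames(m) %||% seq_len(ncol(m)))[sdv == 0], collapse = ", "))
  }
  x <- sweep(sweep(m, 2L, ctr, "-"), 2L, sdv, "/")
  list(x = x, params = list(center = ctr, scale = sdv))
}

#' @rdname standardizeColumns
#' @param params parameter list from a previous `standardizeColumns()` call.
#' @export
applyStandardization <- function(m, params) {
  assertMatrixLike(m, "m")
  sweep(sweep(m, 2L, params$center, "-"), 2L, params$scale, "/")
}

#' @rdname standardizeColumns
#' @param x standardized matrix to map back to the original scale.
#' @export
destandardize <- function(x, params) {
  assertMatrixLike(x, "x")
  sweep(sweep(x, 2L, params$scale, "*"), 2L, params$center, "+")
}
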