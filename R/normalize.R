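# Normalization: batch scale factors and zero-inflated RLE size factors.

#' Batch scale factors
#'
#' For each batch, the scale factor is the ratio of the median of the
#' per-batch total read counts to that batch's total. Multiplying a batch's
#' counts by its factor equalizes sequencing depth across batches without
#' down-sampling every library to the shallowest one.
#'
#' @param x a [CellSet-class] whose `cellInfo` has a `batch` column with at
#'   least two distinct batches, all with positive totals.
#' @return data.frame with one row per batch: `batch`, `total_reads`,
#'   `scale_factor`.
#' @examples
#' # batch totals 100/200/400 give factors 2/1/0.5
#' @export
batchScaleFactors <- function(x) {
  .assertCellSet(x)
  batch <- colData(x)$batch
  if (is.null(batch)) stop("cellInfo must contain a 'batch' column")
  batch <- as.character(batch)
  totals <- tapply(colData(x)$libSize, batch, sum)
  if (length(totals) < 2L) stop("single batch: nothing to normalize")
  if (any(totals == 0))
    stop(sprintf("batch(es) with zero total counts: %s",
                 paste(names(totals)[totals == 0], collapse = ", ")))
  med <- stats::median(totals)
  data.frame(batch = names(totals),
             total_reads = as.numeric(totals),
             scale_factor = as.numeric(med / totals),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize sequencing depth between batches
#'
#' Multiplies every cell's counts by its batch scale factor (see
#' [batchScaleFactors()]). After normalization every batch total equals the
#' pre-normalization median batch total. Values become real-valued; the
#' normalization state moves to `"batch_normalized"` and the operation is
#' refused if the set is not raw.
#'
#' @param x a raw [CellSet-class] with a `batch` column.
#' @return the batch-normalized `CellSet`.
#' @export
normaliseBatches <- function(x) {
  .assertCellSet(x)
  if (x@normState != "raw")
    stop(sprintf("normaliseBatches requires raw counts (current state: %s)",
                 x@normState))
  sf <- batchScaleFactors(x)
  fac <- sf$scale_factor[match(as.character(colData(x)$batch), sf$batch)]
  m <- assay(x, "counts") %*% Matrix::Diagonal(x = fac)
  dimnames(m) <- dimnames(x)
  assay(x, "counts", withDimnames = FALSE) <- .sparsify(m)
  x@normState <- "batch_normalized"
  x <- .recomputeMetrics(x)
  .appendLog(x, "normaliseBatches",
             params = list(scale_factors = stats::setNames(sf$scale_factor, sf$batch)))
}

#' Geometric mean of the strictly positive entries
#'
#' `exp(mean(log(v[v > 0])))`; returns `NA` when no entry is positive
#' (the "undefined" marker used by [rleSizeFactors()]).
#'
#' @param values numeric vector.
#' @return scalar geometric mean, or `NA_real_`.
#' @examples
#' geometricMeanNonzero(c(0, 2, 8))  # 4
#' @export
geometricMeanNonzero <- function(values) {
  pos <- values[values > 0]
  if (!length(pos)) return(NA_real_)
  exp(mean(log(pos)))
}

#' RLE size factors for zero-inflated counts
#'
#' Relative-log-expression size factors adapted to sparse single-cell data:
#' each gene's reference is the geometric mean of its *nonzero* counts
#' across cells (genes never expressed have no reference and are skipped),
#' and each cell's size factor is the median of the ratios
#' `count[g, j] / geomean[g]` over the genes `g` with a nonzero count in
#' that cell. Restricting both the reference and the ratios to true nonzero
#' values keeps the estimator defined under heavy dropout, where the
#' classical RLE geometric mean would collapse to zero.
#'
#' Size factors are reported exactly as computed (no rescaling to unit
#' mean).
#'
#' @param counts genes x cells matrix (dense or sparse), non-negative.
#' @return data.frame with one row per cell: `cell_id`, `size_factor`,
#'   `n_genes_used`.
#' @examples
#' m <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' rleSizeFactors(m)$size_factor  # 1/sqrt(2), sqrt(2)
#' @export
rleSizeFactors <- function(counts) {
  m <- .sparsify(counts)
  if (is.null(colnames(m))) colnames(m) <- paste0("cell", seq_len(ncol(m)))
  nG <- nrow(m)
  logx <- log(m@x)
  rows <- m@i + 1L
  sumLog <- rep(0, nG); nnz <- integer(nG)
  tab <- tabulate(rows, nG)
  agg <- rowsum(logx, rows)
  idx <- as.integer(rownames(agg))
  sumLog[idx] <- agg[, 1L]
  nnz <- tab
  geomean <- ifelse(nnz > 0, exp(sumLog / pmax(nnz, 1L)), NA_real_)

  p <- m@p
  sf <- numeric(ncol(m)); nUsed <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    k <- if (p[j + 1L] > p[j]) (p[j] + 1L):p[j + 1L] else integer(0)
    g <- m@i[k] + 1L
    ok <- !is.na(geomean[g])
    if (!any(ok))
      stop(sprintf("cell '%s' has no usable genes for RLE size-factor estimation (filter it first)",
                   colnames(m)[j]))
    r <- m@x[k][ok] / geomean[g[ok]]
    sf[j] <- stats::median(r)
    nUsed[j] <- sum(ok)
  }
  data.frame(cell_id = colnames(m), size_factor = sf, n_genes_used = nUsed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-cell normalization by zero-inflated RLE
#'
#' Divides every cell's counts by its RLE size factor (see
#' [rleSizeFactors()]). Allowed on raw or batch-normalized sets; the state
#' moves to `"rle_normalized"` and a second application is refused. Size
#' factors are stored in the cell metadata column `sizeFactor`.
#'
#' @param x a [CellSet-class] with `normState` `"raw"` or
#'   `"batch_normalized"`.
#' @return the normalized `CellSet`.
#' @export
normaliseByRLE <- function(x) {
  .assertCellSet(x)
  if (x@normState == "rle_normalized")
    stop("counts are already RLE-normalized")
  sf <- rleSizeFactors(assay(x, "counts"))
  m <- assay(x, "counts") %*% Matrix::Diagonal(x = 1 / sf$size_factor)
  dimnames(m) <- dimnames(x)
  assay(x, "counts", withDimnames = FALSE) <- .sparsify(m)
  cd <- colData(x)
  cd$sizeFactor <- sf$size_factor
  colData(x) <- cd
  x@normState <- "rle_normalized"
  x <- .recomputeMetrics(x)
  .appendLog(x, "normaliseByRLE",
             params = list(median_size_factor = stats::median(sf$size_factor)))
}
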