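# Dimension reduction: variable-gene selection and PCA with
# variance-explained reporting.

#' Select highly variable genes
#'
#' Ranks genes by the variance of `log2(count + 1)` across cells and
#' returns the top `ngenes` identifiers. Ties are broken by lexicographic
#' gene id so the selection is deterministic.
#'
#' @param x a [CellSet-class].
#' @param ngenes number of genes to return; capped at the number of genes
#'   present.
#' @return character vector of gene ids, ordered by decreasing variance.
#' @export
selectVariableGenes <- function(x, ngenes) {
  .assertCellSet(x)
  if (ngenes <= 0) stop("ngenes must be positive")
  ngenes <- min(ngenes, nrow(x))
  m <- assay(x, "counts")
  y <- .sparsify(m)
  y@x <- log2(y@x + 1)
  n <- ncol(y)
  s1 <- Matrix::rowSums(y)
  s2 <- Matrix::rowSums(y^2)
  v <- if (n > 1) (s2 - s1^2 / n) / (n - 1) else rep(0, nrow(y))
  v <- pmax(as.numeric(v), 0)
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(ngenes)]
}

#' Principal component analysis of the expression matrix
#'
#' Computes PCA of the cells on `log2(count + 1)`-transformed expression
#' restricted to the `ngenes` most variable genes. Each gene is centered;
#' with `scaling = TRUE` each gene is also divided by its standard
#' deviation (genes with zero variance are dropped with a warning). The
#' decomposition is an exact singular value decomposition; loading signs
#' are fixed by making each loading vector's largest-magnitude entry
#' positive, so scores are reproducible across platforms.
#'
#' The scores are stored under `reducedDim(x, "pca")` and the full
#' [PCAResult-class] (scores, loadings, per-component variance-explained
#' percentages) under `metadata(x)$pca`.
#'
#' @param x a [CellSet-class]; a warning is issued if the counts are still
#'   raw.
#' @param ngenes number of most-variable genes to use (default 1500).
#' @param scaling standardize genes to unit variance (default TRUE).
#' @param k number of components to retain (default 50, capped at the
#'   matrix rank bound `min(cells, genes used)`).
#' @return the `CellSet` with the PCA stored; retrieve with [pcaResult()].
#' @export
runPCA <- function(x, ngenes = 1500, scaling = TRUE, k = 50) {
  .assertCellSet(x)
  if (x@normState == "raw")
    warning("running PCA on raw (un-normalized) counts")
  genes <- selectVariableGenes(x, ngenes)
  m <- as.matrix(assay(x, "counts")[genes, , drop = FALSE])
  y <- t(log2(m + 1))                      # cells x genes
  mu <- colMeans(y)
  y <- sweep(y, 2L, mu, "-")
  if (scaling) {
    sds <- apply(y, 2L, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      warning(sprintf("dropping %d zero-variance gene(s) before scaling", sum(zero)))
      y <- y[, !zero, drop = FALSE]
      genes <- genes[!zero]
      sds <- sds[!zero]
    }
    y <- sweep(y, 2L, sds, "/")
  }
  maxK <- min(dim(y))
  if (k > maxK)
    stop(sprintf("k = %d exceeds the rank bound %d", k, maxK))
  sv <- svd(y, nu = maxK, nv = maxK)
  ve <- 100 * sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, nrow = maxK)
  loadings <- sv$v
  for (c in seq_len(maxK)) {             # deterministic sign convention
    jmax <- which.max(abs(loadings[, c]))
    if (loadings[jmax, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  loadings <- loadings[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(genes, paste0("PC", seq_len(k)))
  res <- methods::new("PCAResult", scores = scores, loadings = loadings,
                      varianceExplained = ve[seq_len(k)], genesUsed = genes,
                      params = list(ngenes = ngenes, scaling = scaling, k = k))
  reducedDim(x, "pca") <- scores
  metadata(x)$pca <- res
  .appendLog(x, "runPCA", params = list(ngenes = ngenes, scaling = scaling, k = k))
}

#' @describeIn runPCA extract the stored [PCAResult-class].
#' @export
pcaResult <- function(x) {
  .assertCellSet(x)
  res <- metadata(x)$pca
  if (is.null(res)) stop("no PCA stored; run runPCA() first")
  res
}

#' Cumulative variance explained
#'
#' Sum of the variance-explained percentages of the first `firstK`
#' components of a PCA.
#'
#' @param result a [PCAResult-class] (or a [CellSet-class] carrying one).
#' @param firstK number of leading components to sum.
#' @return percentage in (0, 100].
#' @export
varianceExplained <- function(result, firstK) {
  if (methods::is(result, "CellSet")) result <- pcaResult(result)
  if (!methods::is(result, "PCAResult")) stop("expected a PCAResult")
  if (firstK <= 0) stop("firstK must be positive")
  if (firstK > length(result@varianceExplained))
    stop(sprintf("firstK = %d exceeds the %d computed components",
                 firstK, length(result@varianceExplained)))
  sum(result@varianceExplained[seq_len(firstK)])
}

#' @describeIn varianceExplained compact display of a PCA result.
#' @param object a `PCAResult`.
#' @export
setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d cells x %d components (%d genes, scaling=%s)\n",
              nrow(object@scores), ncol(object@scores),
              length(object@genesUsed), object@params$scaling))
  cat(sprintf("variance explained by PC1..PC%d: %.2f%%\n",
              ncol(object@scores), sum(object@varianceExplained)))
})
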