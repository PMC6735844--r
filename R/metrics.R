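# Standalone QC metric computation on a bare count matrix. These are the
# same computations the CellSet runs eagerly after every mutation, exposed
# so metrics can be audited independently of the container.

#' Per-cell quality-control metrics
#'
#' Library size (column sum), number of genes detected (nonzero count),
#' and for each control set the percentage of the library mapped to its
#' genes (0 for cells with an empty library).
#'
#' @param counts genes x cells matrix (dense or sparse) with dimnames.
#' @param controls named list of control gene-id vectors; ids must exist
#'   in the matrix.
#' @return data.frame with one row per cell: `cell_id`, `library_size`,
#'   `n_genes_detected`, and one `pct_<name>` column per control set.
#' @examples
#' m <- matrix(c(2, 3, 0, 5), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' computeCellMetrics(m, controls = list(Mt = "g1"))
#' @export
computeCellMetrics <- function(counts, controls = list()) {
  m <- .sparsify(counts)
  lib <- as.numeric(Matrix::colSums(m))
  out <- data.frame(cell_id = colnames(m) %||% as.character(seq_len(ncol(m))),
                    library_size = lib,
                    n_genes_detected = as.integer(Matrix::colSums(m != 0)),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in names(controls)) {
    g <- controls[[nm]]
    missing <- setdiff(g, rownames(m))
    if (length(missing))
      stop(sprintf("control set '%s' references absent gene id(s): %s",
                   nm, paste(missing, collapse = ", ")))
    ctl <- if (length(g)) as.numeric(Matrix::colSums(m[g, , drop = FALSE])) else 0
    out[[paste0("pct_", nm)]] <- ifelse(lib > 0, 100 * ctl / lib, 0)
  }
  out
}

#' Per-gene quality-control metrics
#'
#' Total counts, number of cells expressing the gene, mean expression per
#' cell, and the gene's percentage of total expression (these sum to 100
#' when the grand total is positive).
#'
#' @param counts genes x cells matrix (dense or sparse) with dimnames.
#' @return data.frame with one row per gene: `gene_id`, `total_counts`,
#'   `n_cells_expressing`, `mean_expression`, `pct_total_expression`.
#' @export
computeGeneMetrics <- function(counts) {
  m <- .sparsify(counts)
  tot <- as.numeric(Matrix::rowSums(m))
  grand <- sum(tot)
  data.frame(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
             total_counts = tot,
             n_cells_expressing = as.integer(Matrix::rowSums(m != 0)),
             mean_expression = tot / max(ncol(m), 1L),
             pct_total_expression = if (grand > 0) 100 * tot / grand else tot * 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
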