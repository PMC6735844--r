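# Internal plumbing shared by all mutating operations: eager metric
# recomputation and the append-only operation log.

.sparsify <- function(m) {
  if (!methods::is(m, "CsparseMatrix")) m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  Matrix::drop0(m)
}

# first offending coordinate of a negative / non-finite value, or NULL
.firstBadCount <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    m <- .sparsify(m)
    bad <- which(is.na(m@x) | !is.finite(m@x) | m@x < 0)
    if (!length(bad)) return(NULL)
    k <- bad[1L]
    j <- which(m@p >= k)[1L] - 1L  # CSC: column j spans p[j] < k <= p[j+1]
    list(i = m@i[k] + 1L, j = j, value = m@x[k])
  } else {
    bad <- which(is.na(m) | !is.finite(m) | m < 0)
    if (!length(bad)) return(NULL)
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    list(i = i, j = j, value = m[i, j])
  }
}

.pctControlCols <- function(x) {
  if (!length(x@controls)) character(0) else paste0("pct_", names(x@controls))
}

# Recompute every QC metric column from the current counts. Called at the
# end of every mutating operation so stored metrics are never stale.
.recomputeMetrics <- function(x) {
  m <- assay(x, "counts")
  lib <- Matrix::colSums(m)
  nz  <- Matrix::colSums(m != 0)
  cd <- colData(x)
  cd$libSize <- as.numeric(lib)
  cd$nGenesDetected <- as.integer(nz)
  for (nm in names(x@controls)) {
    g <- x@controls[[nm]]
    ctl <- if (length(g)) as.numeric(Matrix::colSums(m[g, , drop = FALSE])) else numeric(ncol(m))
    pct <- ifelse(lib > 0, 100 * ctl / lib, 0)
    cd[[paste0("pct_", nm)]] <- as.numeric(pct)
  }
  colData(x) <- cd

  tot <- Matrix::rowSums(m)
  grand <- sum(tot)
  rd <- rowData(x)
  rd$totalCounts <- as.numeric(tot)
  rd$nCellsExpressing <- as.integer(Matrix::rowSums(m != 0))
  rd$meanExpression <- as.numeric(tot) / max(ncol(m), 1L)
  rd$pctTotalExpression <- if (grand > 0) 100 * as.numeric(tot) / grand else numeric(nrow(m))
  rowData(x) <- rd
  x
}

.appendLog <- function(x, operation, params = list(),
                       removedCells = character(0), removedGenes = character(0),
                       before = NULL, note = NULL) {
  rec <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    operation = operation,
    params = params,
    removed_cell_ids = as.character(removedCells),
    removed_gene_ids = as.character(removedGenes),
    before = if (is.null(before)) c(genes = nrow(x), cells = ncol(x)) else before,
    after = c(genes = nrow(x), cells = ncol(x))
  )
  if (!is.null(note)) rec$note <- note
  x@opLog <- c(x@opLog, list(rec))
  x
}

# Subset to the given gene/cell ids, intersect control sets, recompute
# metrics and append one log record. All public subsetting funnels here.
.subsetCore <- function(x, keepGenes, keepCells, operation, params = list()) {
  before <- c(genes = nrow(x), cells = ncol(x))
  removedGenes <- setdiff(rownames(x), keepGenes)
  removedCells <- setdiff(colnames(x), keepCells)
  sce <- methods::as(x, "SingleCellExperiment")[keepGenes, keepCells]

  controls <- x@controls
  dropped <- x@controlsDropped
  if (length(removedGenes)) {
    for (nm in names(controls)) {
      gone <- intersect(controls[[nm]], removedGenes)
      if (length(gone)) {
        controls[[nm]] <- setdiff(controls[[nm]], gone)
        dropped[[nm]] <- union(dropped[[nm]], gone)
      }
    }
  }

  y <- methods::new("CellSet", sce,
    controls = controls, controlsDropped = dropped,
    excludedControls = x@excludedControls,
    opLog = x@opLog, normState = x@normState)
  y <- .recomputeMetrics(y)
  .appendLog(y, operation, params,
             removedCells = removedCells, removedGenes = removedGenes,
             before = before)
}

.assertCellSet <- function(x) {
  if (!methods::is(x, "CellSet")) stop("expected a CellSet object")
  invisible(x)
}
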