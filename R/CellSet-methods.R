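#' Create a CellSet
#'
#' Builds the quality-tracked expression container from a gene-by-cell count
#' matrix. Counts are coerced to a sparse `dgCMatrix`; QC metrics are
#' computed immediately and a `"create"` record opens the operation log.
#'
#' Duplicate gene or cell identifiers are de-duplicated deterministically by
#' appending `".1"`, `".2"`, ... to later occurrences; the original
#' identifiers are kept in `geneInfo`/`cellInfo` under `originalId`.
#'
#' @param counts non-negative numeric matrix (dense or sparse), genes as
#'   rows and cells as columns, with row and column names.
#' @param cellInfo optional data.frame/DataFrame of per-cell metadata, one
#'   row per cell (e.g. a `batch` column). Row order must match the columns
#'   of `counts`.
#' @param geneInfo optional per-gene metadata, one row per gene.
#' @param controls named list of character vectors of gene ids defining
#'   control sets (e.g. `list(Mt = ..., Rb = ...)`). Every referenced gene
#'   must be present in `counts`.
#' @return A [CellSet-class] with `normState == "raw"`.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 4, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' cs <- newCellSet(m)
#' cellMetrics(cs)$libSize
#' @export
newCellSet <- function(counts, cellInfo = NULL, geneInfo = NULL,
                       controls = list()) {
  if (is.null(dim(counts))) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and cell column names")
  m <- .sparsify(counts)
  bad <- .firstBadCount(m)
  if (!is.null(bad))
    stop(sprintf("counts contain a negative or non-finite value (%s) at gene row %d, cell column %d",
                 format(bad$value), bad$i, bad$j))

  gi <- rownames(m); ci <- colnames(m)
  if (anyDuplicated(gi)) {
    orig <- gi; gi <- make.unique(gi, sep = ".")
    rownames(m) <- gi
    geneInfo <- .withOriginalId(geneInfo, orig, nrow(m))
  }
  if (anyDuplicated(ci)) {
    orig <- ci; ci <- make.unique(ci, sep = ".")
    colnames(m) <- ci
    cellInfo <- .withOriginalId(cellInfo, orig, ncol(m))
  }

  if (!is.null(cellInfo) && nrow(cellInfo) != ncol(m))
    stop(sprintf("cell axis mismatch: counts has %d cells but cellInfo has %d rows",
                 ncol(m), nrow(cellInfo)))
  if (!is.null(geneInfo) && nrow(geneInfo) != nrow(m))
    stop(sprintf("gene axis mismatch: counts has %d genes but geneInfo has %d rows",
                 nrow(m), nrow(geneInfo)))

  if (length(controls)) {
    if (is.null(names(controls)) || any(names(controls) == ""))
      stop("controls must be a named list")
    for (nm in names(controls)) {
      missing <- setdiff(controls[[nm]], gi)
      if (length(missing))
        stop(sprintf("control set '%s' references absent gene id(s): %s",
                     nm, paste(missing, collapse = ", ")))
    }
  }

  cd <- if (is.null(cellInfo)) DataFrame(row.names = ci) else DataFrame(cellInfo, row.names = ci)
  rd <- if (is.null(geneInfo)) DataFrame(row.names = gi) else DataFrame(geneInfo, row.names = gi)
  sce <- SingleCellExperiment(assays = list(counts = m), colData = cd, rowData = rd)
  x <- methods::new("CellSet", sce,
                    controls = lapply(controls, as.character),
                    controlsDropped = stats::setNames(
                      rep(list(character(0)), length(controls)), names(controls)),
                    excludedControls = character(0),
                    opLog = list(), normState = "raw")
  x <- .recomputeMetrics(x)
  .appendLog(x, "create",
             params = list(n_controls = length(controls)),
             before = c(genes = nrow(x), cells = ncol(x)))
}

.withOriginalId <- function(info, orig, n) {
  if (is.null(info)) info <- data.frame(row.names = seq_len(n))
  info$originalId <- orig
  info
}

# ---- accessors --------------------------------------------------------------

#' Accessors for CellSet components
#'
#' `cellInfo()` and `geneInfo()` return the user metadata columns;
#' `cellMetrics()` and `geneMetrics()` return the auto-maintained QC metric
#' columns (always current with the stored counts); `controlGenes()` returns
#' the control gene sets restricted to genes still present;
#' `operationLog()` returns the append-only list of operation records;
#' `normState()` reports the normalization state.
#'
#' @param x a [CellSet-class].
#' @return `DataFrame`, list or character scalar as appropriate.
#' @name CellSet-accessors
NULL

.metricColsCell <- function(x) c(.CELL_METRIC_COLS, .pctControlCols(x))

#' @rdname CellSet-accessors
#' @export
cellMetrics <- function(x) {
  .assertCellSet(x)
  cols <- intersect(.metricColsCell(x), colnames(colData(x)))
  out <- colData(x)[, cols, drop = FALSE]
  if ("batch" %in% colnames(colData(x))) out$batch <- colData(x)$batch
  out
}

#' @rdname CellSet-accessors
#' @export
geneMetrics <- function(x) {
  .assertCellSet(x)
  rd <- rowData(x)
  rd[, intersect(.GENE_METRIC_COLS, colnames(rd)), drop = FALSE]
}

#' @rdname CellSet-accessors
#' @export
cellInfo <- function(x) {
  .assertCellSet(x)
  cd <- colData(x)
  cd[, setdiff(colnames(cd), .metricColsCell(x)), drop = FALSE]
}

#' @rdname CellSet-accessors
#' @export
geneInfo <- function(x) {
  .assertCellSet(x)
  rd <- rowData(x)
  rd[, setdiff(colnames(rd), .GENE_METRIC_COLS), drop = FALSE]
}

#' @rdname CellSet-accessors
#' @export
controlGenes <- function(x) { .assertCellSet(x); x@controls }

#' @rdname CellSet-accessors
#' @export
operationLog <- function(x) { .assertCellSet(x); x@opLog }

#' @rdname CellSet-accessors
#' @export
normState <- function(x) { .assertCellSet(x); x@normState }

#' @describeIn CellSet-accessors compact summary printed at the console.
#' @param object a `CellSet`.
#' @export
setMethod("show", "CellSet", function(object) {
  cat(sprintf("CellSet: %d genes x %d cells [%s]\n",
              nrow(object), ncol(object), object@normState))
  if (length(object@controls))
    cat("controls:",
        paste(sprintf("%s(%d)", names(object@controls),
                      lengths(object@controls)), collapse = ", "), "\n")
  ops <- vapply(object@opLog, `[[`, character(1), "operation")
  cat(sprintf("operations logged: %d (%s)\n", length(ops),
              paste(utils::tail(ops, 5), collapse = " -> ")))
  if (length(reducedDimNames(object)))
    cat("reduced dims:", paste(reducedDimNames(object), collapse = ", "), "\n")
})

# ---- subsetting -------------------------------------------------------------

#' Subset cells of a CellSet
#'
#' Keeps the requested cells, recomputes all QC metrics on the submatrix and
#' logs the removed cell identifiers.
#'
#' @param x a [CellSet-class].
#' @param keep one of: a character vector of cell ids; a logical vector over
#'   the current cells; or a predicate `function(colData) -> logical`
#'   evaluated on the combined cell metadata + metrics table.
#' @return the subsetted `CellSet`.
#' @export
subsetCells <- function(x, keep) {
  .assertCellSet(x)
  ids <- .resolveKeep(keep, colnames(x), colData(x), "cell")
  if (!length(ids)) stop("all cells removed")
  .subsetCore(x, rownames(x), ids, "subsetCells",
              params = list(n_kept = length(ids)))
}

#' Subset genes of a CellSet
#'
#' Mirror of [subsetCells()] on the gene axis. Control sets are intersected
#' with the kept genes; dropped members are recorded and logged.
#'
#' @param x a [CellSet-class].
#' @param keep character vector of gene ids, a logical vector, or a
#'   predicate over the gene metadata + metrics table.
#' @return the subsetted `CellSet`.
#' @export
subsetGenes <- function(x, keep) {
  .assertCellSet(x)
  ids <- .resolveKeep(keep, rownames(x), rowData(x), "gene")
  if (!length(ids)) stop("all genes removed")
  .subsetCore(x, ids, colnames(x), "subsetGenes",
              params = list(n_kept = length(ids)))
}

.resolveKeep <- function(keep, ids, meta, axis) {
  if (is.function(keep)) {
    sel <- keep(meta)
    if (!is.logical(sel) || length(sel) != length(ids))
      stop(sprintf("%s predicate must return one logical per %s", axis, axis))
    return(ids[which(sel)])
  }
  if (is.logical(keep)) {
    if (length(keep) != length(ids))
      stop(sprintf("logical keep must have length %d", length(ids)))
    return(ids[keep])
  }
  keep <- as.character(keep)
  unknown <- setdiff(keep, ids)
  if (length(unknown))
    stop(sprintf("unknown %s id(s): %s", axis,
                 paste(utils::head(unknown, 5), collapse = ", ")))
  ids[ids %in% keep]
}

#' Remove control genes from the data set
#'
#' Removes every gene belonging to the named control sets (typically after
#' control percentages have served their QC purpose and before dimension
#' reduction). The named sets become empty and are marked excluded.
#'
#' @param x a [CellSet-class].
#' @param control character vector of control-set names, e.g.
#'   `c("Mt", "Rb")`.
#' @return the `CellSet` without the control genes.
#' @export
excludeControlGenes <- function(x, control) {
  .assertCellSet(x)
  unknown <- setdiff(control, names(x@controls))
  if (length(unknown))
    stop(sprintf("unknown control set(s): %s", paste(unknown, collapse = ", ")))
  drop <- unique(unlist(x@controls[control], use.names = FALSE))
  keep <- setdiff(rownames(x), drop)
  if (!length(keep)) stop("all genes removed")
  y <- .subsetCore(x, keep, colnames(x), "excludeControlGenes",
                   params = list(control = control))
  y@excludedControls <- union(y@excludedControls, control)
  y
}

#' @describeIn subsetCells bracket subsetting; equivalent to
#'   `subsetGenes()` then `subsetCells()` with a single `"subset"` log
#'   record.
#' @param i,j gene / cell indices.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", c("CellSet", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  gi <- if (missing(i)) rownames(x) else rownames(x)[.normIndex(i, rownames(x))]
  cj <- if (missing(j)) colnames(x) else colnames(x)[.normIndex(j, colnames(x))]
  if (!length(gi)) stop("all genes removed")
  if (!length(cj)) stop("all cells removed")
  .subsetCore(x, gi, cj, "subset", params = list())
})

.normIndex <- function(idx, ids) {
  if (is.character(idx)) {
    unknown <- setdiff(idx, ids)
    if (length(unknown))
      stop(sprintf("unknown id(s): %s", paste(utils::head(unknown, 5), collapse = ", ")))
    return(match(idx, ids))
  }
  seq_along(ids)[idx]
}
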