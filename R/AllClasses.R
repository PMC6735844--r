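#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData rowData assay<- colData<- rowData<-
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim reducedDim<- reducedDims reducedDimNames
#' @importFrom BiocGenerics counts
#' @importFrom Matrix colSums rowSums t drop0 Diagonal sparseMatrix readMM writeMM
NULL

# Reserved colData / rowData columns holding auto-maintained QC metrics.
# Everything else in colData/rowData is user metadata (cellInfo / geneInfo).
.CELL_METRIC_COLS <- c("libSize", "nGenesDetected")
.GENE_METRIC_COLS <- c("totalCounts", "nCellsExpressing", "meanExpression",
                       "pctTotalExpression")

.NORM_STATES <- c("raw", "batch_normalized", "rle_normalized")

#' CellSet: a quality-tracked single-cell expression container
#'
#' `CellSet` extends [SingleCellExperiment::SingleCellExperiment] with three
#' guarantees aimed at auditable preliminary analysis:
#' \itemize{
#'   \item per-cell and per-gene QC metrics (library size, genes detected,
#'     control-gene percentages, gene totals and prevalence) are recomputed
#'     eagerly after every operation that changes the count matrix, so the
#'     metrics visible through [cellMetrics()] and [geneMetrics()] always
#'     describe the counts currently stored;
#'   \item every mutating operation appends exactly one record to an
#'     append-only operation log ([operationLog()]), including the identifiers
#'     of any cells or genes it removed;
#'   \item the normalization state (`raw`, `batch_normalized`,
#'     `rle_normalized`) is tracked and enforced, so normalization steps
#'     cannot be applied twice or out of order.
#' }
#'
#' Counts are stored as a sparse `dgCMatrix` (genes as rows, cells as
#' columns) and may become real-valued after normalization.
#'
#' @slot controls named list of character vectors; each element is a control
#'   gene set (e.g. mitochondrial, ribosomal) restricted to genes currently
#'   present in the set.
#' @slot controlsDropped named list recording control-set members removed by
#'   gene filtering, so control definitions remain reconstructible.
#' @slot excludedControls character vector of control-set names whose member
#'   genes were removed wholesale via [excludeControlGenes()].
#' @slot opLog list of log records (see [operationLog()]).
#' @slot normState one of `"raw"`, `"batch_normalized"`, `"rle_normalized"`.
#'
#' @seealso [newCellSet()] to construct one, [cellMetrics()],
#'   [geneMetrics()], [operationLog()], [normState()].
#' @export
setClass("CellSet",
  contains = "SingleCellExperiment",
  slots = c(
    controls        = "list",
    controlsDropped = "list",
    excludedControls = "character",
    opLog           = "list",
    normState       = "character"
  ),
  prototype = list(
    controls = list(), controlsDropped = list(),
    excludedControls = character(0), opLog = list(), normState = "raw"
  )
)

setValidity("CellSet", function(object) {
  msg <- character(0)
  m <- assay(object, "counts")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "counts must carry gene row names and cell column names")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "cell ids must be unique")
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0)))
    msg <- c(msg, "counts must be non-negative and finite")
  if (length(object@normState) != 1L || !object@normState %in% .NORM_STATES)
    msg <- c(msg, sprintf("normState must be one of: %s",
                          paste(.NORM_STATES, collapse = ", ")))
  bad <- vapply(object@controls,
                function(g) any(!g %in% rownames(object)), logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("control set(s) %s reference absent genes",
                          paste(names(object@controls)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Principal component analysis result
#'
#' Holds component scores, gene loadings and per-component
#' variance-explained percentages produced by [runPCA()].
#'
#' @slot scores cells x k matrix of component scores.
#' @slot loadings genes_used x k matrix of gene loadings.
#' @slot varianceExplained percentage of total variance per component,
#'   non-increasing; sums to 100 when k equals the full rank.
#' @slot genesUsed gene ids entering the decomposition, in selection order.
#' @slot params list of the parameters used (`ngenes`, `scaling`, `k`).
#' @export
setClass("PCAResult",
  slots = c(scores = "matrix", loadings = "matrix",
            varianceExplained = "numeric", genesUsed = "character",
            params = "list"))

#' CORE clustering result
#'
#' Result of stability-selected hierarchical clustering ([runCORE()],
#' [coreCluster()]): the dendrogram, the partition obtained at each
#' tree-height window, the adjusted Rand index of each partition against the
#' highest-resolution reference, and the selected stable partition.
#'
#' @slot dendrogram the `hclust` tree (Ward linkage on PC-space Euclidean
#'   distances) over the retained cells.
#' @slot windows height fractions (i/nres) at which the tree was cut.
#' @slot heights absolute cut heights corresponding to `windows`.
#' @slot partitions cells x nres integer matrix of canonical cluster labels.
#' @slot nClusters cluster count at each window.
#' @slot ari adjusted Rand index of each window's partition against the
#'   reference, rounded to 2 decimals for stability selection.
#' @slot referenceLabels the initial reference partition (the tree's
#'   largest-gap cut) that scores the windows and flags outliers.
#' @slot selectedWindow index of the selected (most stable) window.
#' @slot stableLabels named integer vector: the canonical partition at the
#'   selected window (labels 1..K by decreasing cluster size).
#' @slot outlierCells cells removed before the final clustering (members of
#'   reference clusters smaller than `minClusterSize`).
#' @slot params list of parameters used.
#' @export
setClass("COREResult",
  slots = c(dendrogram = "ANY", windows = "numeric", heights = "numeric",
            partitions = "matrix", nClusters = "integer", ari = "numeric",
            referenceLabels = "integer",
            selectedWindow = "integer", stableLabels = "integer",
            outlierCells = "character", params = "list"))
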