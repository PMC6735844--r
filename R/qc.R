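# Cell and gene quality-control filters.
#
# Three rules, applied in this order in the standard workflow:
#   1. filterByOutliers   - robust (MAD-based) outlier cells
#   2. filterByControl    - cells dominated by control (Mt/Rb) transcripts
#   3. filterLowAbundanceGenes - genes expressed in too few cells
# Each removal is recorded in the operation log with the removed ids.

#' Robust outlier bounds from the median absolute deviation
#'
#' Returns `median(x) +/- nmads * MAD(x)` where the MAD is scaled by the
#' normal-consistency constant 1.4826 by default (matching [stats::mad()]),
#' so that for Gaussian data the MAD estimates the standard deviation.
#'
#' @param values numeric vector, finite, non-empty.
#' @param nmads number of MADs defining the range (default 3).
#' @param constant MAD scale constant; 1.4826 for normal consistency, 1 for
#'   the raw median absolute deviation.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' madBounds(c(10, 12, 11, 13, 100), nmads = 3)  # flags 100
#' @export
madBounds <- function(values, nmads = 3, constant = 1.4826) {
  if (!length(values)) stop("values must be non-empty")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  med <- stats::median(values)
  s <- stats::mad(values, constant = constant)
  c(lower = med - nmads * s, upper = med + nmads * s)
}

#' Remove outlier cells by library size, genes detected and control content
#'
#' A cell is removed when any of the following holds:
#' \itemize{
#'   \item its library size falls outside `median +/- cellThreshold * MAD`
#'     of the library sizes (two-sided);
#'   \item its number of detected genes falls outside the analogous
#'     two-sided MAD range;
#'   \item for any control set, its control percentage exceeds
#'     `median + controlThreshold * MAD` (upper-sided only: high
#'     mitochondrial/ribosomal content marks dying cells, low content is
#'     not a defect);
#'   \item its library size is zero (always removed).
#' }
#' Bounds are computed globally over all cells on the raw metric values.
#'
#' @param x a [CellSet-class].
#' @param cellThreshold MADs for the two-sided library-size and
#'   genes-detected rules (default 3).
#' @param controlThreshold MADs for the upper-sided control-percentage rule
#'   (default 3).
#' @return the filtered `CellSet`; removals are logged.
#' @export
filterByOutliers <- function(x, cellThreshold = 3, controlThreshold = 3) {
  .assertCellSet(x)
  cd <- colData(x)
  lib <- cd$libSize
  ng <- cd$nGenesDetected
  bl <- madBounds(lib, cellThreshold)
  bg <- madBounds(ng, cellThreshold)
  out <- lib < bl["lower"] | lib > bl["upper"] |
         ng < bg["lower"] | ng > bg["upper"] |
         lib == 0
  for (nm in .pctControlCols(x)) {
    p <- cd[[nm]]
    bp <- madBounds(p, controlThreshold)
    out <- out | p > bp["upper"]
  }
  keep <- colnames(x)[!out]
  if (!length(keep)) stop("all cells removed")
  .subsetCore(x, rownames(x), keep, "filterByOutliers",
              params = list(cell.threshold = cellThreshold,
                            control.threshold = controlThreshold))
}

#' Remove cells dominated by a control gene set
#'
#' Removes cells whose percentage of counts in the named control set is
#' strictly greater than `pctThreshold`; cells exactly at the threshold are
#' kept.
#'
#' @param x a [CellSet-class].
#' @param control name of a control set (e.g. `"Mt"`).
#' @param pctThreshold percentage threshold (e.g. 20 for mitochondrial,
#'   50 for ribosomal content).
#' @return the filtered `CellSet`.
#' @export
filterByControl <- function(x, control, pctThreshold) {
  .assertCellSet(x)
  if (length(control) != 1L || !control %in% names(x@controls))
    stop(sprintf("unknown control set: %s", paste(control, collapse = ", ")))
  p <- colData(x)[[paste0("pct_", control)]]
  keep <- colnames(x)[p <= pctThreshold]
  if (!length(keep)) stop("all cells removed")
  .subsetCore(x, rownames(x), keep, "filterByControl",
              params = list(control = control, pct.threshold = pctThreshold))
}

#' Remove genes expressed in too small a fraction of cells
#'
#' Removes genes whose prevalence `100 * nCellsExpressing / nCells` is
#' strictly below `pctThreshold`; genes exactly at the threshold are kept.
#'
#' @param x a [CellSet-class].
#' @param pctThreshold prevalence threshold in percent (default 0.1: genes
#'   must appear in at least 0.1\% of cells).
#' @return the filtered `CellSet`.
#' @export
filterLowAbundanceGenes <- function(x, pctThreshold = 0.1) {
  .assertCellSet(x)
  prev <- 100 * rowData(x)$nCellsExpressing / ncol(x)
  keep <- rownames(x)[prev >= pctThreshold]
  if (!length(keep)) stop("all genes removed")
  .subsetCore(x, keep, colnames(x), "filterLowAbundanceGenes",
              params = list(pct.threshold = pctThreshold))
}
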