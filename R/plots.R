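# Diagnostic plots. Every figure has a numeric data twin so downstream
# checks (and the pipeline report) assert numbers, not pixels.

#' @importFrom ggplot2 ggplot aes geom_boxplot geom_violin geom_line
#'   geom_point geom_segment labs theme_minimal scale_y_continuous facet_wrap
NULL

#' General quality-control plots
#'
#' Per-batch library-size boxplot, expression boxplot of the 25 most
#' abundant genes (largest share of total expression, ties by gene id),
#' and violin plots of the control-gene percentage per cell for each
#' control set.
#'
#' @param x a [CellSet-class].
#' @param nTop number of most abundant genes to show (default 25).
#' @return list with `data` (named list of data.frames) and `plots`
#'   (named list of ggplot objects).
#' @export
plotGeneralQC <- function(x, nTop = 25) {
  .assertCellSet(x)
  cd <- colData(x)
  batch <- if ("batch" %in% colnames(cd)) as.character(cd$batch) else "all"
  lib <- data.frame(cell_id = colnames(x), batch = batch,
                    library_size = cd$libSize, stringsAsFactors = FALSE)

  rd <- rowData(x)
  ord <- order(-rd$pctTotalExpression, rownames(x))
  top <- rownames(x)[ord][seq_len(min(nTop, nrow(x)))]
  m <- as.matrix(assay(x, "counts")[top, , drop = FALSE])
  topLong <- data.frame(
    gene_id = factor(rep(top, each = ncol(m)), levels = top),
    cell_id = rep(colnames(m), times = length(top)),
    expression = as.vector(t(m)), stringsAsFactors = FALSE)

  ctl <- do.call(rbind, lapply(names(controlGenes(x)), function(nm)
    data.frame(cell_id = colnames(x), batch = batch, control = nm,
               pct = cd[[paste0("pct_", nm)]], stringsAsFactors = FALSE)))

  plots <- list(
    librarySize = ggplot(lib, aes(x = batch, y = library_size)) +
      geom_boxplot() + theme_minimal() +
      labs(title = "Library size by batch", y = "library size"),
    topAbundant = ggplot(topLong, aes(x = gene_id, y = expression)) +
      geom_boxplot() + theme_minimal() +
      labs(title = sprintf("Top %d most abundant genes", length(top))) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1)))
  if (!is.null(ctl))
    plots$controlPct <- ggplot(ctl, aes(x = batch, y = pct)) +
      geom_violin(scale = "width") + facet_wrap(~control) + theme_minimal() +
      labs(title = "Control-gene percentage per cell", y = "% of library")

  list(data = list(librarySizes = lib, topAbundant = topLong, controlPct = ctl),
       plots = plots)
}

#' Normalization quality-control plots
#'
#' Compares the expression distribution of named genes before and after
#' normalization.
#'
#' @param before,after the [CellSet-class] before and after normalization
#'   (same cells).
#' @param geneList character vector of gene ids to display; absent genes
#'   are an error.
#' @return list with `data` (long data.frame: gene, cell, stage,
#'   expression) and `plots`.
#' @export
plotNormQC <- function(before, after, geneList) {
  .assertCellSet(before); .assertCellSet(after)
  missing <- setdiff(geneList, intersect(rownames(before), rownames(after)))
  if (length(missing))
    stop(sprintf("gene(s) not present: %s", paste(missing, collapse = ", ")))
  grab <- function(s, stage) {
    m <- as.matrix(assay(s, "counts")[geneList, , drop = FALSE])
    data.frame(gene_id = rep(geneList, each = ncol(m)),
               cell_id = rep(colnames(m), times = length(geneList)),
               stage = stage, expression = as.vector(t(m)),
               stringsAsFactors = FALSE)
  }
  d <- rbind(grab(before, "before"), grab(after, "after"))
  d$stage <- factor(d$stage, levels = c("before", "after"))
  p <- ggplot(d, aes(x = stage, y = log2(expression + 1))) +
    geom_violin(scale = "width") + facet_wrap(~gene_id) + theme_minimal() +
    labs(title = "Expression before / after normalization",
         y = "log2(expression + 1)")
  list(data = d, plots = list(normQC = p))
}

#' Scree plot of a PCA
#'
#' @param result a [PCAResult-class] (or a [CellSet-class] carrying one).
#' @return list with `data` (component, percent_variance) and `plots`.
#' @export
plotPCAVariance <- function(result) {
  if (methods::is(result, "CellSet")) result <- pcaResult(result)
  d <- data.frame(component = seq_along(result@varianceExplained),
                  percent_variance = result@varianceExplained)
  p <- ggplot(d, aes(x = component, y = percent_variance)) +
    geom_line() + geom_point() + theme_minimal() +
    labs(title = "Scree plot", y = "% variance explained")
  list(data = d, plots = list(scree = p))
}

# dendrogram segment coordinates from an hclust object
.hclustSegments <- function(hc) {
  n <- length(hc$order)
  leafX <- numeric(n); leafX[hc$order] <- seq_len(n)
  mergeX <- numeric(nrow(hc$merge)); mergeH <- hc$height
  segs <- vector("list", nrow(hc$merge))
  childXH <- function(v) {
    if (v < 0) c(leafX[-v], 0) else c(mergeX[v], mergeH[v])
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- childXH(hc$merge[k, 1L]); b <- childXH(hc$merge[k, 2L])
    mergeX[k] <- (a[1L] + b[1L]) / 2
    segs[[k]] <- data.frame(
      x = c(a[1L], b[1L], a[1L]), xend = c(a[1L], b[1L], b[1L]),
      y = c(a[2L], b[2L], mergeH[k]), yend = c(mergeH[k], mergeH[k], mergeH[k]))
  }
  do.call(rbind, segs)
}

#' CORE clustering diagnostic plots
#'
#' A cluster-labeled dendrogram and a stability curve (cluster count and
#' ARI against cut height across the windows). The numeric twin of the
#' stability curve is [coreStabilityTable()].
#'
#' @param result a [COREResult-class].
#' @return list with `data` (`stability`, `leaves`) and `plots`
#'   (`dendrogram`, `stability`).
#' @export
plotCORE <- function(result) {
  if (!methods::is(result, "COREResult")) stop("expected a COREResult")
  stab <- coreStabilityTable(result)
  hc <- result@dendrogram
  segs <- .hclustSegments(hc)
  n <- length(hc$order)
  leafX <- numeric(n); leafX[hc$order] <- seq_len(n)
  leaves <- data.frame(cell_id = hc$labels, x = leafX,
                       cluster = factor(result@stableLabels[hc$labels]),
                       stringsAsFactors = FALSE)
  dendro <- ggplot(segs) +
    geom_segment(aes(x = x, xend = xend, y = y, yend = yend)) +
    geom_point(data = leaves, aes(x = x, y = 0, colour = cluster), size = 0.8) +
    theme_minimal() +
    labs(title = "CORE dendrogram", x = NULL, y = "merge height") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  stabLong <- rbind(
    data.frame(window = stab$window, metric = "n_clusters", value = stab$n_clusters),
    data.frame(window = stab$window, metric = "ari", value = stab$ari))
  stability <- ggplot(stabLong, aes(x = window, y = value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~metric, scales = "free_y", ncol = 1) + theme_minimal() +
    labs(title = "Cluster-count and stability across resolutions")
  list(data = list(stability = stab, leaves = leaves),
       plots = list(dendrogram = dendro, stability = stability))
}
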