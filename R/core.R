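# CORE: stability-selected hierarchical clustering.
#
# Cells are clustered by Ward-linkage hierarchical clustering on Euclidean
# distances in PC space. An initial reference partition (the tree's
# largest merge-height gap) flags outliers; the dendrogram is then cut at
# nres evenly spaced tree-height windows, each partition is scored by its
# adjusted Rand index against the reference, and the most stable partition
# (the one whose rounded ARI attains the maximum) is selected.

#' Euclidean distance matrix in PC space
#'
#' @param scores cells x k score matrix (e.g. from [runPCA()]).
#' @param dims number of leading components to use.
#' @return a [stats::dist] object over the cells.
#' @export
pcDistanceMatrix <- function(scores, dims) {
  if (dims <= 0) stop("dims must be positive")
  if (dims > ncol(scores))
    stop(sprintf("dims = %d exceeds the %d available components", dims, ncol(scores)))
  stats::dist(scores[, seq_len(dims), drop = FALSE], method = "euclidean")
}

#' Ward-linkage dendrogram
#'
#' Agglomerative hierarchical clustering with Ward's criterion on squared
#' Euclidean distances (`hclust` method `"ward.D2"`: merge heights are on
#' the original distance scale).
#'
#' @param distances a [stats::dist] object.
#' @return an `hclust` tree.
#' @export
buildDendrogram <- function(distances) {
  n <- attr(distances, "Size")
  if (is.null(n) || n < 2) stop("need at least 2 items to build a dendrogram")
  stats::hclust(distances, method = "ward.D2")
}

#' Cut a dendrogram at a height and canonicalize the labels
#'
#' Clusters are the connected components after removing merges above `h`.
#' Labels are canonical: 1..K assigned by decreasing cluster size, ties by
#' the smallest member index.
#'
#' @param dendrogram an `hclust` tree.
#' @param h cut height (>= 0).
#' @return named integer vector of cluster labels, one per leaf.
#' @export
cutAtHeight <- function(dendrogram, h) {
  if (h < 0) stop("height must be non-negative")
  canonicalizeLabels(stats::cutree(dendrogram, h = h))
}

#' Canonical cluster labels
#'
#' Relabels an arbitrary partition so that cluster 1 is the largest,
#' cluster 2 the next largest, and so on; among equal-sized clusters the
#' one containing the earliest item gets the smaller label.
#'
#' @param labels vector of cluster assignments (any label type).
#' @return integer vector of labels 1..K, names preserved.
#' @export
canonicalizeLabels <- function(labels) {
  f <- as.character(labels)
  sizes <- table(f)
  firstIdx <- vapply(names(sizes), function(l) which(f == l)[1L], integer(1))
  ord <- names(sizes)[order(-as.integer(sizes), firstIdx)]
  out <- match(f, ord)
  names(out) <- names(labels)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent random partitions. Computed from the contingency table of
#' the two labelings with the permutation-model expectation.
#'
#' @param p1,p2 cluster label vectors over the same items (same length; if
#'   both are named, names must match).
#' @return scalar ARI.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 3))  # 4/7
#' @export
adjustedRandIndex <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions cover different item sets")
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions cover different item sets")
    p2 <- p2[names(p1)]
  }
  tab <- table(p1, p2)
  n <- length(p1)
  sumij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxindex <- (a + b) / 2
  if (maxindex == expected) return(1)   # both partitions trivial
  (sumij - expected) / (maxindex - expected)
}

#' Natural reference partition of a dendrogram
#'
#' Cuts the tree at its largest merge-height gap: for each candidate
#' cluster count `k` in `2..kmax`, the gap is the height interval within
#' which a cut yields exactly `k` clusters; the `k` with the widest
#' interval is the tree's most clear-cut number of clusters. Ties go to
#' the smaller `k`. Returns canonical labels; a tree whose merges all sit
#' at one height (no structure) yields a single cluster.
#'
#' This partition serves as the initial clustering of [coreCluster()]:
#' it flags outlier cells and is the reference against which the windowed
#' cuts are scored.
#'
#' @param dendrogram an `hclust` tree.
#' @param kmax largest cluster count considered (default 40).
#' @return named integer vector of canonical cluster labels.
#' @export
gapReferencePartition <- function(dendrogram, kmax = 40) {
  h <- dendrogram$height
  n <- length(h) + 1L
  ks <- 2:min(kmax, n)
  gaps <- vapply(ks, function(k) {
    upper <- h[n - k + 1L]
    lower <- if (n - k >= 1L) h[n - k] else 0
    upper - lower
  }, numeric(1))
  if (max(gaps) <= 0) {
    labels <- rep(1L, n)
    names(labels) <- dendrogram$labels
    return(labels)
  }
  canonicalizeLabels(stats::cutree(dendrogram, k = ks[which.max(gaps)]))
}

#' CORE clustering of a score matrix
#'
#' The scores-level engine behind [runCORE()]; operate directly on any
#' cells x k embedding.
#'
#' Algorithm: (1) Ward dendrogram on Euclidean distances over the first
#' `dims` components; (2) an initial reference partition is obtained by
#' cutting the tree at its largest merge-height gap (the dendrogram's
#' natural cluster count, searched over 2..`nres` clusters) — this plays
#' the role of the initial branch cut that flags outliers; (3) if
#' `removeOutliers`, cells in reference clusters smaller than
#' `minClusterSize` are removed and the tree and reference are rebuilt;
#' (4) the tree is cut at heights `(i/nres) * H`, `i = 1..nres`, `H` the
#' tree height; (5) every window's partition is scored by its adjusted
#' Rand index against the reference, rounded to 2 decimals; (6) among
#' windows with at least 2 clusters attaining the maximal rounded ARI,
#' the largest height (fewest clusters) is selected when
#' `conservative = FALSE`, the smallest height (most clusters) when
#' `conservative = TRUE`.
#'
#' @param scores cells x k numeric matrix with unique row names.
#' @param dims leading components to use (default 20).
#' @param nres number of tree-height windows (default 40).
#' @param removeOutliers drop tiny clusters at the finest cut before the
#'   windowed analysis (default TRUE).
#' @param conservative tie-break toward more clusters (TRUE) or fewer
#'   (FALSE, default).
#' @param minClusterSize reference clusters smaller than this are outliers
#'   (default 3).
#' @param maxOutlierFrac if the flagged outliers exceed this fraction of
#'   cells the initial cut is considered uninformative for outlier
#'   detection and no cell is removed, with a warning (default 0.2).
#' @return a [COREResult-class].
#' @export
coreCluster <- function(scores, dims = 20, nres = 40, removeOutliers = TRUE,
                        conservative = FALSE, minClusterSize = 3,
                        maxOutlierFrac = 0.2) {
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("cell", seq_len(nrow(scores)))
  if (nres < 2) stop("nres must be at least 2")
  if (nrow(scores) < 2 * minClusterSize)
    stop(sprintf("need at least %d cells (2 x minClusterSize)", 2 * minClusterSize))
  dims <- min(dims, ncol(scores))
  params <- list(dims = dims, nres = nres, removeOutliers = removeOutliers,
                 conservative = conservative, minClusterSize = minClusterSize)

  hc <- buildDendrogram(pcDistanceMatrix(scores, dims))
  ref <- gapReferencePartition(hc, kmax = nres)
  outliers <- character(0)
  if (removeOutliers) {
    sizes <- table(ref)
    small <- as.integer(names(sizes)[sizes < minClusterSize])
    if (length(small)) {
      flagged <- rownames(scores)[ref %in% small]
      if (length(flagged) > maxOutlierFrac * nrow(scores)) {
        warning(sprintf(
          "initial cut flags %d/%d cells as outliers; skipping outlier removal",
          length(flagged), nrow(scores)))
      } else {
        outliers <- flagged
        keep <- setdiff(rownames(scores), outliers)
        scores <- scores[keep, , drop = FALSE]
        hc <- buildDendrogram(pcDistanceMatrix(scores, dims))
        ref <- gapReferencePartition(hc, kmax = nres)
      }
    }
  }

  H <- max(hc$height)
  windows <- seq_len(nres) / nres
  heights <- windows * H
  parts <- matrix(NA_integer_, nrow(scores), nres,
                  dimnames = list(rownames(scores), NULL))
  for (i in seq_len(nres)) parts[, i] <- cutAtHeight(hc, heights[i])
  nClusters <- apply(parts, 2L, max)
  ari <- round(vapply(seq_len(nres), function(i)
    adjustedRandIndex(parts[, i], ref), numeric(1)), 2)

  multi <- which(nClusters >= 2L)
  if (!length(multi)) {
    warning("every window yields a single cluster; returning the trivial partition")
    selected <- nres
  } else {
    best <- max(ari[multi])
    cand <- multi[ari[multi] == best]
    selected <- if (conservative) min(cand) else max(cand)
  }
  labels <- canonicalizeLabels(parts[, selected])

  methods::new("COREResult", dendrogram = hc, windows = windows,
               heights = heights, partitions = parts,
               nClusters = as.integer(nClusters), ari = ari,
               referenceLabels = ref,
               selectedWindow = as.integer(selected), stableLabels = labels,
               outlierCells = outliers, params = params)
}

#' Stability-selected clustering of a CellSet
#'
#' Runs [coreCluster()] on the stored PCA scores. Outlier cells (tiny
#' clusters of the initial reference cut) are removed from the returned set — their
#' identifiers are retained in the operation log — and the stable cluster
#' labels are written to the cell metadata column `cluster`. The full
#' [COREResult-class] is stored under `metadata(x)$core`.
#'
#' @param x a [CellSet-class] with a `"pca"` reduced dimension.
#' @param dims,nres,removeOutliers,conservative,minClusterSize,maxOutlierFrac
#'   see [coreCluster()]. `dims` defaults to 20 leading components.
#' @return the clustered `CellSet` (without outlier cells).
#' @export
runCORE <- function(x, dims = 20, nres = 40, removeOutliers = TRUE,
                    conservative = FALSE, minClusterSize = 3,
                    maxOutlierFrac = 0.2) {
  .assertCellSet(x)
  if (!"pca" %in% reducedDimNames(x))
    stop("no 'pca' reduced dimension; run runPCA() first")
  scores <- reducedDim(x, "pca")
  if (dims > ncol(scores))
    stop(sprintf("dims = %d exceeds the %d stored components", dims, ncol(scores)))
  res <- coreCluster(scores, dims = dims, nres = nres,
                     removeOutliers = removeOutliers,
                     conservative = conservative,
                     minClusterSize = minClusterSize,
                     maxOutlierFrac = maxOutlierFrac)
  if (length(res@outlierCells)) {
    x <- .subsetCore(x, rownames(x), setdiff(colnames(x), res@outlierCells),
                     "runCORE.removeOutliers",
                     params = list(minClusterSize = minClusterSize))
  }
  cd <- colData(x)
  cd$cluster <- as.integer(res@stableLabels[colnames(x)])
  colData(x) <- cd
  metadata(x)$core <- res
  .appendLog(x, "runCORE",
             params = list(dims = dims, nres = nres,
                           conservative = conservative,
                           n_clusters = res@nClusters[res@selectedWindow]))
}

#' @describeIn runCORE extract the stored [COREResult-class].
#' @export
coreResult <- function(x) {
  .assertCellSet(x)
  res <- metadata(x)$core
  if (is.null(res)) stop("no CORE result stored; run runCORE() first")
  res
}

#' @describeIn runCORE the stable cluster label of every cell, as stored in
#'   the cell metadata.
#' @export
clusterLabels <- function(x) {
  .assertCellSet(x)
  lab <- colData(x)$cluster
  if (is.null(lab)) stop("no cluster labels; run runCORE() first")
  stats::setNames(as.integer(lab), colnames(x))
}

#' @describeIn coreCluster compact display of a CORE result.
#' @param object a `COREResult`.
#' @export
setMethod("show", "COREResult", function(object) {
  k <- object@nClusters[object@selectedWindow]
  cat(sprintf("COREResult: %d cells, %d windows, selected window %d (%d cluster%s)\n",
              nrow(object@partitions), length(object@windows),
              object@selectedWindow, k, if (k == 1) "" else "s"))
  if (length(object@outlierCells))
    cat(sprintf("outlier cells removed: %d\n", length(object@outlierCells)))
})

#' Stability table of a CORE result
#'
#' One row per tree-height window: the cut height, the number of clusters
#' and the (rounded) ARI against the reference partition. This is the
#' numeric twin of the stability curve in [plotCORE()].
#'
#' @param result a [COREResult-class].
#' @return data.frame with columns `window`, `height`, `n_clusters`, `ari`.
#' @export
coreStabilityTable <- function(result) {
  if (!methods::is(result, "COREResult")) stop("expected a COREResult")
  data.frame(window = seq_along(result@windows),
             height = result@heights,
             n_clusters = result@nClusters,
             ari = result@ari,
             row.names = NULL)
}
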