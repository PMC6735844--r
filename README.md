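# cellcore

Quality-tracked preliminary analysis of single-cell RNA-seq count
matrices, for analysts who want the standard early pipeline — QC,
filtering, normalization, PCA, clustering, differential expression —
with every step auditable and every removal logged.

The package is built around four pieces of methodology:

* **A quality-tracked container.** `CellSet` (an extension of
  `SingleCellExperiment`) recomputes per-cell and per-gene QC metrics
  after every mutation and keeps an append-only log of operations with
  the identifiers of removed cells and genes, so an analysis is
  replayable from its log.
* **Zero-inflation-aware RLE size factors.** Per gene, the reference is
  the geometric mean over *nonzero* counts; per cell *j*, the size
  factor is the median of x<sub>gj</sub>/geomean<sub>&gt;0</sub>(g)
  over the genes expressed in that cell. This keeps relative-log-
  expression normalization defined under heavy dropout. Batch depth is
  equalized separately by scaling each batch by
  median(batch totals)/batch total.
* **CORE clustering (clustering at optimal resolution).** Ward-linkage
  hierarchical clustering on PC-space distances, cut at 40 evenly
  spaced tree heights; each partition is scored by its adjusted Rand
  index against an initial reference cut (the tree's largest
  merge-height gap), and the most stable cluster number is selected.
  Outlier cells flagged by the initial cut are removed and logged.
* **A combined two-part likelihood-ratio test.** Differential
  expression sums a discrete (binomial, on/off) deviance and a
  continuous (normal on log2 expression among expressing cells, shared
  variance) deviance, referred to a chi-square with 2 df (1 df when
  only the discrete part is testable), with a variance floor so
  zero-variance genes remain testable. Suitable for strongly imbalanced
  cluster sizes where dispersion-fitting methods fail to converge.

A zero-inflated negative-binomial simulator with planted clusters,
batches, control genes and DE genes (`simulateCounts()`) makes the
whole pipeline testable without downloading data.

## Worked example

A complete run on simulated data — three planted cell populations, two
sequencing batches, mitochondrial/ribosomal controls, 5% dying cells:

```r
library(cellcore)

sim <- simulateCellSet(simConfig(
  nGenes = 800, clusterSizes = c(150, 120, 80),
  batchMultipliers = c(1, 1.5), deGenesPerCluster = 50, deLog2FC = 3,
  mtFrac = 0.02, rbFrac = 0.05, dyingFrac = 0.05, seed = 7))
cs <- sim$set
cs
#> CellSet: 800 genes x 350 cells [raw]
#> controls: Mt(16), Rb(40)
#> operations logged: 1 (create)

cs <- filterByOutliers(cs, cellThreshold = 3, controlThreshold = 3)
cs <- filterByControl(cs, "Mt", 20)
cs <- filterByControl(cs, "Rb", 50)
cs <- filterLowAbundanceGenes(cs, 0.1)
cs
#> CellSet: 798 genes x 330 cells [raw]
#> controls: Mt(16), Rb(40)
#> operations logged: 5 (create -> filterByOutliers -> filterByControl ->
#>                       filterByControl -> filterLowAbundanceGenes)
```

QC removed 20 cells (outliers and high-mitochondrial "dying" cells) and
2 never-expressed genes; the log records exactly which. Normalize,
reduce, cluster:

```r
cs <- normaliseByRLE(cs)
cs <- excludeControlGenes(cs, c("Mt", "Rb"))
cs <- runPCA(cs, ngenes = 500, scaling = TRUE, k = 20)
varianceExplained(cs, 10)
#> [1] 21.84115

cs <- runCORE(cs, dims = 10, nres = 40)
coreResult(cs)
#> COREResult: 330 cells, 40 windows, selected window 36 (3 clusters)
table(clusterLabels(cs))
#>   1   2   3
#> 142 113  75
```

The first 10 PCs carry 21.8% of the variance; the stability selection
lands on 3 clusters, matching the planted populations (the recovered
sizes 142/113/75 are the planted 150/120/80 minus the filtered cells).
Differential expression of cluster 1 against the rest:

```r
de <- runDiffExpression(cs, "cluster", 1, c(2, 3))
head(de[, c("gene_id", "lrt_statistic", "df", "p_value", "adjusted_p",
            "log2_fold_change")], 5)
#>      gene_id lrt_statistic df      p_value   adjusted_p log2_fold_change
#> 2  Gene00002      337.8243  2 4.389217e-74 3.256799e-71         3.198789
#> 37 Gene00037      334.1673  2 2.732141e-73 2.027249e-70         2.928441
#> 8  Gene00008      331.6479  2 9.628831e-73 7.144593e-70         3.246306
#> 13 Gene00013      328.4702  2 4.716388e-72 3.499560e-69         3.071771
#> 14 Gene00014      327.7737  2 6.681216e-72 4.957463e-69         3.017390

sum(de$adjusted_p < 0.05 & abs(de$log2_fold_change) > 2, na.rm = TRUE)
#> [1] 85
```

The top genes are planted markers of cluster 1 (log2 fold changes near
the planted value 3); 85 genes pass Bonferroni 0.05 with |log2FC| > 2.

Everything can also be driven declaratively (`runPipeline()`), which
writes a plain-text bundle plus TSV tables (clusters, stability curve,
scree, size factors, DE) and is byte-deterministic given a seed.
`writeBundle()`/`readBundle()` round-trip a `CellSet` losslessly
through a directory of Matrix Market + TSV + JSON files;
`readDenseCounts()` and `readMTXBundle()` import expression matrices
(10x-style triplet bundles or dense TSV with batch suffixes in the
barcodes).

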