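---
title: "Methods and design of cellcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of cellcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcore)
```

cellcore covers the preliminary analysis of single-cell RNA-seq count
matrices: quality control and filtering, normalization, dimension
reduction, stability-selected clustering, and differential expression.
This vignette explains the statistical models behind each step, the
parameters that matter, the design choices that were genuinely open, and
what the package's validation does and does not establish.

## The quality-tracked container

All analyses operate on a `CellSet`, an extension of
`SingleCellExperiment` holding a sparse genes-by-cells count matrix. Two
behaviours distinguish it from a plain container:

* **Eager metric synchronization.** Per-cell metrics (library size,
  genes detected, percentage of counts in each control gene set) and
  per-gene metrics (total counts, prevalence, share of total expression)
  are recomputed at the end of every operation that changes the matrix.
  Eager rather than lazy recomputation was chosen because it makes the
  "metrics always describe the current counts" contract trivially
  auditable: at any point, recomputing from scratch must reproduce the
  stored values bit for bit (integer metrics) or to 1e-12 (ratios), and
  the test suite asserts exactly that.
* **An append-only operation log.** Every mutating operation appends one
  record carrying its parameters and the identifiers of any removed
  cells or genes. Replaying the log against the original object must
  reproduce the final object; this is also asserted by tests. The log
  doubles as the mechanism that enforces step ordering (a set cannot be
  batch-normalized twice, nor RLE-normalized after it already was).

Counts are held as a `dgCMatrix` throughout; no operation densifies the
full matrix (PCA densifies only the selected variable-gene block).

## Quality control

Cell quality is summarized by robust statistics. For a metric vector
$x$, the outlier range is $\mathrm{median}(x) \pm n_{\mathrm{mads}}
\cdot 1.4826\,\mathrm{MAD}(x)$; the constant 1.4826 makes the MAD a
consistent estimator of the standard deviation under normality and
matches R's `mad()`. `filterByOutliers()` removes cells outside the
range for library size or genes detected (two-sided, default
$n_{\mathrm{mads}} = 3$), cells whose control-gene percentage exceeds
the *upper* bound only (high mitochondrial or ribosomal content marks
dying cells; unusually low content is not a defect), and cells with an
empty library (they carry no information and break downstream ratios).
Bounds are computed globally across batches, matching a workflow in
which filtering is applied to the aggregated experiment.

Two further rules use fixed thresholds: `filterByControl()` removes
cells whose control percentage strictly exceeds a threshold (20% is a
common mitochondrial cutoff, 50% ribosomal), and
`filterLowAbundanceGenes()` removes genes expressed in strictly fewer
than a given percentage of cells (default 0.1%). Comparisons are strict
so that cells or genes sitting exactly at a printed threshold are kept.
All filters are idempotent in the threshold-based cases; the MAD filter
recomputes its bounds on the filtered data, so a second pass can in
principle remove further cells.

## Normalization

**Between batches.** Each batch's scale factor is the ratio of the
median per-batch total count to that batch's total; multiplying a
batch's cells by its factor equalizes depth without down-sampling every
library to the shallowest one. After `normaliseBatches()` every batch
total equals the pre-normalization median (a conservation property the
tests check to 1e-9 relative). Normalized counts are deliberately not
rounded back to integers: rounding would corrupt the size-factor
arithmetic downstream.

**Between cells.** `normaliseByRLE()` adapts relative-log-expression
size factors to zero inflation. For gene $g$, the reference is the
geometric mean of its counts over the cells where it is nonzero; for
cell $j$, the size factor is
$$ s_j = \mathrm{median}_{\,g\,:\,x_{gj} > 0}\; x_{gj} / \mathrm{geomean}_{>0}(g), $$
and normalized expression is $x_{gj}/s_j$. Restricting both the
reference and the ratios to true nonzero values keeps the estimator
defined under heavy dropout, where a classical geometric mean over all
cells would be zero for most genes. The median was chosen as the
aggregation statistic — it is the standard robust RLE estimator and
resists distortion by differentially expressed genes; a mean would be
cheaper but fragile. Size factors are reported exactly as computed,
with no rescaling to unit mean, so they are reproducible from the
definition alone. Cells that express no genes at all have no defined
factor and must be filtered first; the error names the offending cell.

## Dimension reduction

`runPCA()` operates on $\log_2(x + 1)$-transformed expression of the
`ngenes` most variable genes (variance of the log-transformed values,
ties broken lexicographically by gene id). The log transform is the
ecosystem convention for variance stabilization of counts and matches
the scale the differential-expression model uses; the
workflow default is `ngenes = 1500` with `scaling = TRUE`
(unit-variance genes). Genes with zero variance cannot be scaled and
are dropped with a warning.

The decomposition is an exact singular value decomposition in all
cases. A randomized solver would only pay off far beyond the problem
sizes this package targets, and exactness buys bit-reproducible scores.
Signs are fixed by making the largest-magnitude entry of each loading
vector positive (ties resolved to the first index), so scores do not
flip between platforms. Variance explained per component is
$100\,d_i^2 / \sum_k d_k^2$; at full rank the percentages sum to 100,
and the test suite cross-checks them against eigenvalues of the dense
covariance matrix on small instances.

## CORE clustering

Cells are clustered hierarchically (Ward linkage on Euclidean distances
over the first `dims` principal components, default 20; the `hclust`
`ward.D2` convention, i.e. merge heights on the original distance
scale). The clustering question CORE answers is not "cut the tree
where?" but "which cluster number is stable across cut heights?":

1. An **initial reference partition** is obtained by cutting the tree
   at its largest merge-height gap: for each candidate cluster count
   $k \in \{2, \dots, \texttt{nres}\}$, the width of the height
   interval yielding exactly $k$ clusters is measured, and the widest
   interval wins (ties to smaller $k$). This is the tree's most
   clear-cut cluster count and serves the role of an initial
   branch-pruning cut. We chose this rule after establishing
   empirically that using the finest height window as reference
   degenerates on realistic data: with noisy counts, the leaf level of
   the tree fragments into many medium-sized chunks (both the tree
   height and the top within-cluster merges grow as $\sqrt{n}$, so no
   sample size escapes this), the fragmented finest partition never
   agrees with the true-cluster plateau, and the selection collapses
   onto the fragments. The largest-gap reference is deterministic,
   cheap, and robust to leaf noise.
2. Cells in reference clusters smaller than `minClusterSize` (default
   3) are **outliers**: they are removed, recorded in the result and in
   the operation log, and the tree and reference are rebuilt. If the
   initial cut flags more than `maxOutlierFrac` (default 20%) of all
   cells, it is deemed uninformative and nothing is removed (with a
   warning) — a guard against discarding real structure.
3. The tree is cut at `nres` (default 40) evenly spaced heights
   $h_i = (i/\texttt{nres}) \cdot H$ with $H$ the tree height, giving a
   partition and cluster count per window (counts are non-increasing in
   height).
4. Each window's partition is scored by its **adjusted Rand index**
   against the reference, rounded to two decimals. Among windows with
   at least two clusters that attain the maximal rounded ARI, the
   default (`conservative = FALSE`) selects the largest height — the
   fewest clusters consistent with maximal stability; `conservative =
   TRUE` selects the smallest height (the most clusters). If every
   window yields a single cluster (a tree with no structure, e.g.
   identical cells) the trivial one-cluster result is returned with a
   warning.

Labels are canonicalized everywhere (1..K by decreasing cluster size,
ties to the cluster containing the earliest cell), which makes results
invariant to cell input order. The ARI implementation is exact
contingency-table arithmetic and is tested for exact agreement with an
independent reference implementation.

The distance matrix is the memory ceiling: $n$ cells need
$O(n^2)$ doubles (about 3 GB at 20,000 cells), which bounds the
practical problem size of `runCORE()`.

## Differential expression

`runDiffExpression()` compares a cluster against the remaining clusters
(or any two label sets) with a combined two-part likelihood-ratio test
per gene, designed for zero-inflated data and robust to strongly
imbalanced group sizes:

* **Discrete part** — expression on/off. With $z$ of $n$ cells
  expressing the gene in each group, the binomial deviance
  $D_{\mathrm{disc}} = 2[\ell(\hat\pi_a) + \ell(\hat\pi_b) -
  \ell(\hat\pi_{\mathrm{pooled}})]$ is computed with the
  $0 \log 0 = 0$ convention.
* **Continuous part** — expression level among expressing cells.
  $y = \log_2(x)$ over positive counts is modelled as normal with
  group-specific means and a shared variance; the deviance compares the
  separate-means fit to the pooled fit, using maximum-likelihood
  ($1/z$) variance denominators so the statistic is a pure likelihood
  ratio. This part is testable only when both groups have at least one
  expressing cell and the pooled positive-value variance is positive.
* Variances are floored at $\varepsilon = 10^{-8}$ before likelihood
  evaluation, so genes expressed at a single value (zero within-group
  variance) remain testable: if both groups sit at the same value the
  continuous part contributes nothing, while different single values
  produce a large but finite statistic.

The combined statistic $D_{\mathrm{disc}} + D_{\mathrm{cont}}$ is
referred to $\chi^2_2$ ($\chi^2_1$ when only the discrete part is
testable). Genes expressed in no cell of either group get `NA` p-values
and are excluded from the multiple-testing count. Cell detection rate
is deliberately not modelled as a covariate. The statistic is validated
against a brute-force numerical maximization of the two-part likelihood
(agreement to 1e-6) and for type-I calibration at the nominal 5% level
under null simulations.

Fold changes are reported as
$\log_2((\bar x_a + \delta)/(\bar x_b + \delta))$ with pseudo-mean
$\delta = 1$ by default: adding $\delta$ on the normalized-mean scale
keeps the ratio finite for genes absent in one group and shrinks
estimates for lowly expressed genes toward zero, where raw ratios are
dominated by sampling noise. Multiple-testing correction goes through
`stats::p.adjust` (Bonferroni or Benjamini-Hochberg).

## The count simulator

`simulateCounts()` generates data with the statistical structure the
pipeline assumes, so every claim above is testable without downloads:
gene baseline means are lognormal (`meanlog = 1`, `sdlog = 1.5`: a
right-skewed distribution with median expression near 3 counts, as in
shallow droplet data); counts are negative binomial (`dispersion = 2`,
i.e. substantially overdispersed); sequencing depth differs between
batches by multiplicative factors; dropout is an extra Bernoulli zero
mask with probability logistic in $-\log\mu$ (`dropoutA = 0.5`,
`dropoutB = 1`: a gene at mean 1 loses about 38% of its draws, a gene
at mean 100 almost none), so lowly expressed genes drop out more;
planted clusters differ by blocks of genes at a chosen
$\log_2$ fold change; control genes are named to match the standard
mitochondrial (`Mt-*`) and ribosomal (`Rps*`/`Rpl*`) patterns so the
control-detection path is exercised end to end; and an optional
fraction of "dying" cells has mitochondrial means inflated. Fixed seeds
give bit-reproducible output via R's portable RNG.

The simulator does **not** emulate gene-gene correlation within
clusters, ambient RNA, doublets, UMI saturation, or batch effects
beyond depth. Passing tests therefore establish that the algorithms are
implemented correctly and behave as designed on data matching their
assumptions — not that those assumptions hold for any particular real
experiment.

## Validation problem sizes and numerical choices

The test and validation runs use deliberately compact problem sizes:
workflows of roughly 500–1,000 genes and 200–600 cells, null
calibration on 2,000 genes at 100 cells per group, blob-recovery runs
of 150 cells over 20 seeds. These sizes put the clustering step inside
its operating regime (separation large relative to within-cluster
spread in PC space) while keeping each suite run in seconds.

Numerical conventions collected in one place: MAD constant 1.4826
(configurable to 1); strict threshold comparisons; variance floor
$10^{-8}$ in the LRT; ARI rounded to 2 decimals only for stability
selection; PCA sign fixing by largest loading entry; variable-gene ties
by id; canonical cluster labels by size then first appearance; bundle
round-trip exact for integer counts and full double precision
otherwise; Matrix Market files 1-based on disk.

## Known limitations

* The MAD filter's bounds are global, not per batch; with extreme
  depth imbalance, filter after `normaliseBatches()` or subset by
  batch first.
* The largest-gap reference assumes the true cluster structure creates
  the dominant height gap; nested designs with very unequal separations
  may need `conservative = TRUE` or a different `dims`.
* The continuous LRT component assumes log-normal positive expression
  with a shared variance; strongly bimodal within-group expression will
  inflate the statistic.
* `runCORE()` holds a dense distance matrix; beyond ~20,000 cells,
  subsample or use fewer cells per run.
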