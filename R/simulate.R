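# Zero-inflated negative-binomial count simulator.
#
# Emulates the statistical structure the pipeline assumes: gene-specific
# lognormal baseline means, NB sampling noise, multiplicative batch depth
# effects, logistic-in-log-mean dropout (lowly expressed genes drop out
# more), planted cell clusters distinguished by log2 fold-change DE genes,
# control genes named to match the mitochondrial/ribosomal regexes, and an
# optional "dying" cell fraction with elevated mitochondrial content.

#' Simulation configuration
#'
#' Collects and validates the parameters of [simulateCounts()]. Defaults
#' describe a small but realistic droplet-style experiment: ~1,000 genes,
#' lognormal baseline means (median ~e, right-skewed), NB dispersion
#' `size = 2`, moderate dropout, 2\% mitochondrial and 5\% ribosomal
#' control genes.
#'
#' @param nGenes total number of genes.
#' @param clusterSizes integer vector: cells per planted cluster.
#' @param batchMultipliers positive multipliers of sequencing depth, one
#'   per batch; cells are assigned to batches in round-robin order so
#'   every cluster spans every batch.
#' @param meanlog,sdlog lognormal hyperparameters of the baseline gene
#'   means.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param dropoutA,dropoutB dropout model `p_zero = 1/(1 + exp(a + b*log(mu)))`;
#'   with the defaults a gene at mean 1 loses ~38\% of its draws, a gene
#'   at mean 100 almost none. `dropoutB = Inf` disables dropout.
#' @param deGenesPerCluster number of genes upregulated in each cluster
#'   (disjoint blocks among the non-control genes).
#' @param deLog2FC log2 fold change of the planted DE genes.
#' @param mtFrac,rbFrac fractions of genes named as mitochondrial
#'   (`Mt-*`) / ribosomal (`Rps*`/`Rpl*`) controls.
#' @param dyingFrac fraction of cells with mitochondrial means inflated by
#'   `dyingMtMultiplier` (emulating dying cells caught by QC).
#' @param dyingMtMultiplier mitochondrial inflation factor for dying cells.
#' @param seed RNG seed; fixed seed gives bit-reproducible output.
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(nGenes = 1000, clusterSizes = 200,
                      batchMultipliers = 1,
                      meanlog = 1, sdlog = 1.5, dispersion = 2,
                      dropoutA = 0.5, dropoutB = 1,
                      deGenesPerCluster = 0, deLog2FC = 3,
                      mtFrac = 0.02, rbFrac = 0.05,
                      dyingFrac = 0, dyingMtMultiplier = 10,
                      seed = 1) {
  stopifnot(nGenes >= 1, all(clusterSizes >= 1), all(batchMultipliers > 0),
            dispersion > 0, mtFrac >= 0, rbFrac >= 0, mtFrac + rbFrac < 1,
            dyingFrac >= 0, dyingFrac <= 1)
  nMt <- round(mtFrac * nGenes); nRb <- round(rbFrac * nGenes)
  nFree <- nGenes - nMt - nRb
  if (deGenesPerCluster * length(clusterSizes) > nFree)
    stop("DE gene blocks exceed the number of non-control genes")
  structure(list(
    nGenes = as.integer(nGenes), clusterSizes = as.integer(clusterSizes),
    batchMultipliers = as.numeric(batchMultipliers),
    meanlog = meanlog, sdlog = sdlog, dispersion = dispersion,
    dropoutA = dropoutA, dropoutB = dropoutB,
    deGenesPerCluster = as.integer(deGenesPerCluster), deLog2FC = deLog2FC,
    nMt = nMt, nRb = nRb,
    dyingFrac = dyingFrac, dyingMtMultiplier = dyingMtMultiplier,
    seed = as.integer(seed)), class = "simConfig")
}

.simGeneNames <- function(cfg) {
  mt <- if (cfg$nMt) paste0("Mt-", seq_len(cfg$nMt)) else character(0)
  rb <- if (cfg$nRb) {
    half <- ceiling(cfg$nRb / 2)
    c(paste0("Rps", seq_len(half)),
      if (cfg$nRb > half) paste0("Rpl", seq_len(cfg$nRb - half)))
  } else character(0)
  n <- cfg$nGenes - cfg$nMt - cfg$nRb
  c(mt, rb, sprintf("Gene%05d", seq_len(n)))
}

#' Simulate a gene-by-cell count matrix with known structure
#'
#' Draws `counts[g, j] ~ Dropout(NB(mu_gj, dispersion))` with
#' `mu_gj = base_g * 2^(effect if g is DE in cluster(j)) * batchMult(j)`,
#' then applies an independent Bernoulli zero mask with probability
#' logistic in `-log(mu)`. Returns the counts together with the ground
#' truth needed for parameter-recovery tests.
#'
#' @param config a [simConfig()].
#' @return list with `counts` (sparse genes x cells, dimnames set),
#'   `cellInfo` (data.frame: `cell_barcode`, `batch`), and `truth`
#'   (list: `clusters` named integer, `batches` named character,
#'   `de` data.frame of planted DE genes, `dyingCells`, `geneMeans`).
#' @export
simulateCounts <- function(config) {
  cfg <- if (inherits(config, "simConfig")) config else do.call(simConfig, config)
  set.seed(cfg$seed)
  nC <- sum(cfg$clusterSizes); nG <- cfg$nGenes
  nB <- length(cfg$batchMultipliers)
  geneIds <- .simGeneNames(cfg)

  clusters <- rep(seq_along(cfg$clusterSizes), cfg$clusterSizes)
  batchIdx <- rep_len(seq_len(nB), nC)
  barcodes <- sprintf("Cell%05d.%d", seq_len(nC), batchIdx)

  base <- stats::rlnorm(nG, cfg$meanlog, cfg$sdlog)
  mu <- matrix(base, nG, nC)

  de <- NULL
  if (cfg$deGenesPerCluster > 0) {
    firstFree <- cfg$nMt + cfg$nRb
    de <- do.call(rbind, lapply(seq_along(cfg$clusterSizes), function(k) {
      idx <- firstFree + (k - 1L) * cfg$deGenesPerCluster + seq_len(cfg$deGenesPerCluster)
      data.frame(gene_id = geneIds[idx], gene_index = idx, cluster = k,
                 log2fc = cfg$deLog2FC, stringsAsFactors = FALSE)
    }))
    for (k in seq_along(cfg$clusterSizes)) {
      idx <- de$gene_index[de$cluster == k]
      mu[idx, clusters == k] <- mu[idx, clusters == k] * 2^cfg$deLog2FC
    }
  }

  dying <- character(0)
  if (cfg$dyingFrac > 0 && cfg$nMt > 0) {
    nDying <- round(cfg$dyingFrac * nC)
    if (nDying > 0) {
      dyingIdx <- sample.int(nC, nDying)
      mu[seq_len(cfg$nMt), dyingIdx] <- mu[seq_len(cfg$nMt), dyingIdx] * cfg$dyingMtMultiplier
      dying <- barcodes[sort(dyingIdx)]
    }
  }

  mu <- sweep(mu, 2L, cfg$batchMultipliers[batchIdx], "*")
  counts <- matrix(stats::rnbinom(nG * nC, size = cfg$dispersion, mu = mu), nG, nC)
  if (is.finite(cfg$dropoutB)) {
    pZero <- 1 / (1 + exp(cfg$dropoutA + cfg$dropoutB * log(mu)))
    counts[matrix(stats::runif(nG * nC), nG, nC) < pZero] <- 0L
  }
  dimnames(counts) <- list(geneIds, barcodes)

  list(counts = .sparsify(counts),
       cellInfo = data.frame(cell_barcode = barcodes,
                             batch = as.character(batchIdx),
                             stringsAsFactors = FALSE),
       truth = list(clusters = stats::setNames(clusters, barcodes),
                    batches = stats::setNames(as.character(batchIdx), barcodes),
                    de = de, dyingCells = dying,
                    geneMeans = stats::setNames(base, geneIds)))
}

#' Simulate a CellSet with detected controls
#'
#' Convenience wrapper: runs [simulateCounts()] and builds a
#' [CellSet-class] with mitochondrial/ribosomal control sets detected by
#' the standard name patterns (`^Mt-`, `^Rps|^Rpl`, case-insensitive),
#' exercising the same control-detection path used on real data.
#'
#' @param config a [simConfig()].
#' @return list with `set` (the CellSet) and `truth`.
#' @export
simulateCellSet <- function(config) {
  sim <- simulateCounts(config)
  ids <- rownames(sim$counts)
  controls <- list()
  mt <- grep("^Mt-", ids, ignore.case = TRUE, value = TRUE)
  rb <- grep("^Rps|^Rpl", ids, ignore.case = TRUE, value = TRUE)
  if (length(mt)) controls$Mt <- mt
  if (length(rb)) controls$Rb <- rb
  ci <- sim$cellInfo; rownames(ci) <- ci$cell_barcode
  list(set = newCellSet(sim$counts, cellInfo = ci, controls = controls),
       truth = sim$truth)
}

#' Two count matrices drawn from one identical law
#'
#' Null-simulation helper for type-I-error calibration: both groups share
#' the same lognormal gene means, NB dispersion and dropout model, so any
#' differential-expression call on them is a false positive.
#'
#' @param nGenes number of genes.
#' @param nPerGroup cells per group.
#' @param seed RNG seed.
#' @param ... further parameters passed to [simConfig()].
#' @return list of two genes x cells matrices `a` and `b` sharing row
#'   names.
#' @export
simulateNullPair <- function(nGenes, nPerGroup, seed, ...) {
  stopifnot(nGenes >= 1, nPerGroup >= 2)
  cfg <- simConfig(nGenes = nGenes, clusterSizes = 2 * nPerGroup,
                   mtFrac = 0, rbFrac = 0, seed = seed, ...)
  sim <- simulateCounts(cfg)
  m <- sim$counts
  list(a = m[, seq_len(nPerGroup), drop = FALSE],
       b = m[, nPerGroup + seq_len(nPerGroup), drop = FALSE])
}
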