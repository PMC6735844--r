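# Shared fixtures and independent oracles used across the suite.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

tinyCounts <- function() {
  matrix(c(1, 0, 2,
           0, 4, 0), nrow = 2, byrow = TRUE,
         dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
}

randomCountSet <- function(nGenes, nCells, seed, controls = FALSE) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nCells, lambda = 2), nGenes, nCells,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("c%03d.%d", seq_len(nCells),
                                      rep_len(1:2, nCells))))
  ci <- data.frame(batch = rep_len(c("1", "2"), nCells),
                   row.names = colnames(m))
  ctl <- if (controls) list(Mt = rownames(m)[1:2]) else list()
  newCellSet(m, cellInfo = ci, controls = ctl)
}

# isotropic Gaussian blobs in an embedding space, with truth labels
makeBlobScores <- function(sizes, centers, sigma, seed, k = 5) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  sc <- matrix(rnorm(n * k, sd = sigma), n, k)
  for (d in seq_len(ncol(centers))) sc[, d] <- sc[, d] + centers[lab, d]
  rownames(sc) <- sprintf("cell%03d", seq_len(n))
  colnames(sc) <- paste0("PC", seq_len(k))
  list(scores = sc, truth = stats::setNames(lab, rownames(sc)))
}

# O(n^3) naive Ward agglomeration (ward.D2 convention) via the
# Lance-Williams update on squared distances; returns sorted merge heights.
naiveWardHeights <- function(points) {
  n <- nrow(points)
  d2 <- as.matrix(dist(points))^2
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestVal <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      i <- active[ai]; j <- active[bi]
      if (d2[i, j] < bestVal) { bestVal <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestVal))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Numeric-maximization oracle for the two-part LRT: maximizes the discrete
# (binomial) and continuous (shared-variance normal on log2 positives)
# log-likelihoods by direct optimization instead of plugging in MLEs.
bruteTwoPartLRT <- function(a, b, epsVar = 1e-8) {
  za <- sum(a > 0); zb <- sum(b > 0); na <- length(a); nb <- length(b)
  binLL <- function(p, z, n) {
    p <- min(max(p, 1e-12), 1 - 1e-12)
    z * log(p) + (n - z) * log(1 - p)
  }
  maxBin <- function(z, n)
    optimize(binLL, c(1e-12, 1 - 1e-12), z = z, n = n, maximum = TRUE,
             tol = 1e-12)$objective
  llDiscAlt <- maxBin(za, na) + maxBin(zb, nb)
  llDiscNull <- maxBin(za + zb, na + nb)

  ya <- log2(a[a > 0]); yb <- log2(b[b > 0]); y <- c(ya, yb)
  normLL <- function(mu, v, x) sum(dnorm(x, mu, sqrt(v), log = TRUE))
  llContAlt <- llContNull <- 0
  if (za >= 1 && zb >= 1 && sum((y - mean(y))^2) > 0) {
    altFn <- function(par)
      -(normLL(par[1], max(exp(par[3]), epsVar), ya) +
        normLL(par[2], max(exp(par[3]), epsVar), yb))
    nullFn <- function(par)
      -normLL(par[1], max(exp(par[2]), epsVar), y)
    v0 <- max(var(y) * (length(y) - 1) / length(y), 1e-4)
    oa <- optim(c(mean(ya), mean(yb), log(v0)), altFn,
                method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 20000))
    on <- optim(c(mean(y), log(v0)), nullFn, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 20000))
    llContAlt <- -oa$value; llContNull <- -on$value
  }
  2 * ((llDiscAlt + llContAlt) - (llDiscNull + llContNull))
}

# random non-degenerate two-group count vectors for LRT oracle checks
randomLRTCase <- function() {
  repeat {
    na <- sample(6:20, 1); nb <- sample(6:20, 1)
    a <- rpois(na, lambda = runif(1, 0.5, 6))
    b <- rpois(nb, lambda = runif(1, 0.5, 6))
    ya <- a[a > 0]; yb <- b[b > 0]
    if (length(ya) >= 2 && length(yb) >= 2 &&
        var(log2(ya)) + var(log2(yb)) > 1e-3) return(list(a = a, b = b))
  }
}

expect_setsEqual <- function(x, y) expect_true(setequal(x, y))
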