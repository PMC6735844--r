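test_that("PC-space distances are Euclidean over the requested dimensions", {
  sc <- rbind(a = c(0, 0, 9), b = c(3, 4, 9))
  d <- pcDistanceMatrix(sc, 2)
  expect_equal(as.numeric(d), 5)
  expect_equal(as.numeric(pcDistanceMatrix(sc, 1)), 3)  # later columns ignored
  expect_equal(as.numeric(pcDistanceMatrix(rbind(a = 1:2, b = 1:2), 2)), 0)
  expect_error(pcDistanceMatrix(sc, 0), "positive")
  expect_error(pcDistanceMatrix(sc, 5), "exceeds")
})

test_that("Ward dendrogram merges nearest structure first", {
  pts <- matrix(c(0, 1, 10), ncol = 1,
                dimnames = list(c("p0", "p1", "p10"), NULL))
  hc <- buildDendrogram(dist(pts))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))   # 0 and 1 merge first
  expect_true(hc$height[2] > hc$height[1])

  pairs <- matrix(c(0, 0.1, 5, 5.1, 20, 20.1, 25, 25.1), ncol = 1,
                  dimnames = list(paste0("q", 1:8), NULL))
  hc2 <- buildDendrogram(dist(pairs))
  part <- cutAtHeight(hc2, mean(range(hc2$height)))
  expect_equal(max(part), 2)
  expect_error(buildDendrogram(dist(matrix(1))), "at least 2")
})

test_that("Ward merge heights agree with a naive O(n^3) agglomeration oracle", {
  set.seed(3)
  pts <- matrix(rnorm(40), 20, 2)
  hc <- buildDendrogram(dist(pts))
  expect_equal(sort(hc$height), naiveWardHeights(pts), tolerance = 1e-9)
})

test_that("tree cutting spans singletons to one cluster with canonical labels", {
  set.seed(4)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("c", 1:12), NULL))
  hc <- buildDendrogram(dist(pts))
  expect_equal(max(cutAtHeight(hc, max(hc$height))), 1)
  expect_equal(max(cutAtHeight(hc, min(hc$height) * 0.99)), 12)

  pairs <- matrix(c(0, 0.1, 8, 8.1), ncol = 1,
                  dimnames = list(paste0("q", 1:4), NULL))
  hcp <- buildDendrogram(dist(pairs))
  part <- cutAtHeight(hcp, 1)
  expect_equal(unname(part), c(1, 1, 2, 2))  # canonical: earliest cluster = 1
  expect_error(cutAtHeight(hcp, -1), "non-negative")
})

test_that("canonical labels order clusters by size then first appearance", {
  lab <- c(x1 = "b", x2 = "a", x3 = "a", x4 = "b", x5 = "a", x6 = "c")
  out <- canonicalizeLabels(lab)
  expect_equal(unname(out), c(2, 1, 1, 2, 1, 3))
  expect_equal(names(out), names(lab))
})

test_that("adjusted Rand index matches hand computation and edge cases", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 9, 9)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 3)), 4 / 7)
  expect_equal(adjustedRandIndex(rep(1, 4), 1:4), 0)
  p1 <- c(a = 1, b = 1, c = 2); p2 <- c(c = 2, a = 1, b = 1)
  expect_equal(adjustedRandIndex(p1, p2), 1)   # aligned by name
  expect_error(adjustedRandIndex(1:3, 1:4), "different item sets")
  expect_error(adjustedRandIndex(c(a = 1, b = 1), c(a = 1, z = 2)),
               "different item sets")
})

test_that("ARI agrees exactly with an independent reference on random pairs", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    p1 <- sample(1:sample(2:6, 1), n, replace = TRUE)
    p2 <- sample(1:sample(2:6, 1), n, replace = TRUE)
    expect_equal(adjustedRandIndex(p1, p2),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
})

test_that("three separated blobs are recovered at the selected window", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  blob <- makeBlobScores(c(50, 50, 50), centers, sigma = 0.1, seed = 11)
  res <- coreCluster(blob$scores, dims = 5, nres = 40)
  expect_equal(res@nClusters[res@selectedWindow], 3L)
  expect_equal(adjustedRandIndex(res@stableLabels, blob$truth[names(res@stableLabels)]), 1)
  expect_equal(res@ari[1], 1)                       # reference window
  expect_true(all(diff(res@nClusters) <= 0))        # monotone in height
  expect_equal(length(res@windows), 40)
})

test_that("a degenerate structureless tree yields the trivial one-cluster result", {
  # identical cells: every merge sits at height zero, every window gives
  # one cluster
  sc <- matrix(1, 12, 3, dimnames = list(paste0("c", 1:12), NULL))
  expect_warning(res <- coreCluster(sc, dims = 2, nres = 10,
                                    removeOutliers = FALSE),
                 "single cluster")
  expect_equal(res@nClusters[res@selectedWindow], 1L)
  expect_true(all(res@stableLabels == 1))
  expect_true(all(res@referenceLabels == 1))
})

test_that("conservative selection never chooses fewer clusters", {
  centers <- rbind(c(0, 0), c(3, 0), c(20, 0), c(23, 0))
  blob <- makeBlobScores(rep(40, 4), centers, sigma = 0.3, seed = 12)
  cons <- coreCluster(blob$scores, dims = 2, nres = 40, conservative = TRUE)
  lib <- coreCluster(blob$scores, dims = 2, nres = 40, conservative = FALSE)
  expect_gte(cons@nClusters[cons@selectedWindow],
             lib@nClusters[lib@selectedWindow])
})

test_that("clustering is invariant to cell input order", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  blob <- makeBlobScores(c(30, 25, 20), centers, sigma = 0.15, seed = 13)
  res1 <- coreCluster(blob$scores, dims = 5, nres = 20)
  set.seed(99)
  perm <- sample(nrow(blob$scores))
  res2 <- coreCluster(blob$scores[perm, ], dims = 5, nres = 20)
  ids <- rownames(blob$scores)
  expect_equal(res1@stableLabels[ids], res2@stableLabels[ids])
})

test_that("outlier cells are detected, removed and reported", {
  centers <- rbind(c(0, 0), c(8, 0))
  blob <- makeBlobScores(c(40, 40), centers, sigma = 0.2, seed = 14)
  sc <- rbind(blob$scores,
              far1 = c(100, 100, 0, 0, 0), far2 = c(-100, 50, 0, 0, 0))
  res <- coreCluster(sc, dims = 2, nres = 20, minClusterSize = 3)
  expect_setsEqual(res@outlierCells, c("far1", "far2"))
  expect_false(any(c("far1", "far2") %in% names(res@stableLabels)))
  expect_equal(res@nClusters[res@selectedWindow], 2L)
})

test_that("runCORE stores labels, logs outliers and validates inputs", {
  sim <- simulateCellSet(simConfig(nGenes = 400, clusterSizes = c(60, 60, 60),
                                   deGenesPerCluster = 60, deLog2FC = 4,
                                   mtFrac = 0, rbFrac = 0, seed = 15))
  s <- normaliseByRLE(sim$set)
  expect_error(runCORE(s), "runPCA")
  s <- runPCA(s, ngenes = 300, k = 20)
  s2 <- runCORE(s, dims = 10, nres = 40)
  expect_equal(sort(unique(colData(s2)$cluster)), 1:3)
  expect_equal(adjustedRandIndex(colData(s2)$cluster,
                                 sim$truth$clusters[colnames(s2)]), 1)
  expect_error(runCORE(s, dims = 50), "exceeds")
})
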