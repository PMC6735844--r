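test_that("identical groups give a zero statistic and p = 1", {
  r <- combinedLRT(c(0, 2, 4), c(0, 2, 4))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p.value, 1)
  expect_equal(r$df, 2L)
})

test_that("all-zero group reduces to the discrete binomial test with df 1", {
  r <- combinedLRT(c(0, 0, 0, 0), c(3, 5, 2, 4))
  expect_equal(r$df, 1L)
  # closed form: 0/4 vs 4/4, pooled 1/2 -> deviance 16 log 2
  expect_equal(r$statistic, 16 * log(2), tolerance = 1e-12)
  expect_equal(r$p.value, pchisq(16 * log(2), 1, lower.tail = FALSE))
  expect_error(combinedLRT(numeric(0), 1), "at least one cell")
})

test_that("statistic matches a brute-force numeric MLE oracle", {
  set.seed(21)
  # planted strong continuous shift
  a <- rbinom(100, 1, 0.8) * 2^rnorm(100, 4, 0.8)
  b <- rbinom(100, 1, 0.8) * 2^rnorm(100, 6, 0.8)
  r <- combinedLRT(a, b)
  expect_equal(r$statistic, bruteTwoPartLRT(a, b), tolerance = 1e-6)
  expect_lt(r$p.value, 1e-6)

  for (i in 1:100) {
    cs <- randomLRTCase()
    expect_equal(combinedLRT(cs$a, cs$b)$statistic,
                 bruteTwoPartLRT(cs$a, cs$b), tolerance = 1e-6)
  }
})

test_that("statistic is non-negative, symmetric and scale-invariant", {
  set.seed(22)
  for (i in 1:50) {
    a <- rpois(sample(3:15, 1), runif(1, 0.3, 5))
    b <- rpois(sample(3:15, 1), runif(1, 0.3, 5))
    r <- combinedLRT(a, b)
    expect_gte(r$statistic, 0)
    expect_equal(r$statistic, combinedLRT(b, a)$statistic, tolerance = 1e-10)
    # scaling both groups shifts all log-expressions by a constant:
    # discrete part unchanged (zeros preserved), continuous part
    # location-invariant
    r2 <- combinedLRT(a * 8, b * 8)
    expect_equal(r2$statistic, r$statistic, tolerance = 1e-9)
    expect_equal(r2$df, r$df)
  }
})

test_that("zero-variance genes stay testable through the variance floor", {
  # both groups single-valued and equal: no continuous evidence
  r <- combinedLRT(c(4, 4, 4, 0), c(4, 4, 0, 0))
  expect_equal(r$df, 1L)   # pooled positive variance is zero
  # single-valued but different: strong continuous evidence, finite stat
  r2 <- combinedLRT(c(4, 4, 4), c(16, 16, 16))
  expect_equal(r2$df, 2L)
  expect_true(is.finite(r2$statistic) && r2$statistic > 50)
  expect_lt(r2$p.value, 1e-10)
})

test_that("p-value adjustment matches the standard procedures", {
  expect_equal(adjustPValues(0.01, "bonferroni"), 0.01)
  expect_equal(adjustPValues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjustPValues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))   # hand step-up: min_k (m/k) p_(k) from the top
  expect_equal(adjustPValues(c(0.5, NA, 0.01), "bonferroni"),
               c(1, NA, 0.02))  # NAs excluded from m
  expect_error(adjustPValues(c(0.5, 1.2)), "0, 1")
})

test_that("adjusted fold change behaves as a shrunken log ratio", {
  expect_equal(foldChange(3, 3), 0)
  expect_equal(foldChange(4, 0, delta = 1), log2(5))
  expect_equal(foldChange(2, 7, 0.5), -foldChange(7, 2, 0.5))
  expect_error(foldChange(1, 1, delta = 0), "positive")
})

test_that("runDiffExpression validates groups and orders results", {
  sim <- simulateCellSet(simConfig(nGenes = 120, clusterSizes = c(40, 40),
                                   deGenesPerCluster = 10, deLog2FC = 3,
                                   mtFrac = 0, rbFrac = 0, seed = 23))
  s <- normaliseByRLE(sim$set)
  cd <- colData(s); cd$cluster <- sim$truth$clusters[colnames(s)]
  colData(s) <- cd
  tab <- runDiffExpression(s, "cluster", 1, 2)
  expect_equal(nrow(tab), nrow(s))
  expect_true(!is.unsorted(tab$p_value, na.rm = TRUE))
  expect_true(all(tab$adjusted_p >= tab$p_value, na.rm = TRUE))
  tested <- !is.na(tab$p_value)
  expect_true(all(tab$df[tested] %in% c(1L, 2L)))
  # planted genes dominate the top of the table
  top <- head(tab$gene_id, 20)
  expect_gte(length(intersect(top, sim$truth$de$gene_id)), 15)

  expect_error(runDiffExpression(s, "cluster", 1, 1), "overlap")
  expect_error(runDiffExpression(s, "cluster", 1, 9), "unknown group label")
  expect_error(runDiffExpression(s, "nope", 1, 2), "no cell metadata column")
})

test_that("genes identical across groups are null; absent genes get NA", {
  base <- matrix(rpois(40, 3) + 1, 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("a", 1:10)))
  m <- cbind(base, base)
  colnames(m) <- c(paste0("a", 1:10), paste0("b", 1:10))
  m <- rbind(m, silent = 0)
  ci <- data.frame(grp = rep(c("A", "B"), each = 10),
                   row.names = colnames(m))
  s <- newCellSet(m, cellInfo = ci)
  tab <- runDiffExpression(s, "grp", "A", "B")
  expressed <- tab[tab$gene_id != "silent", ]
  expect_true(all(abs(expressed$p_value - 1) < 1e-12))
  expect_true(all(expressed$log2_fold_change == 0))
  silent <- tab[tab$gene_id == "silent", ]
  expect_true(is.na(silent$p_value) && is.na(silent$adjusted_p))
  # m for correction counts only testable genes
  expect_equal(expressed$adjusted_p, pmin(expressed$p_value * 4, 1))
})
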