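makeBatchSet <- function(totals) {
  # one gene per batch cell; each batch is a single cell with the given total
  m <- matrix(totals, nrow = 1,
              dimnames = list("g1", paste0("c", seq_along(totals))))
  ci <- data.frame(batch = paste0("B", seq_along(totals)),
                   row.names = colnames(m))
  newCellSet(m, cellInfo = ci)
}

test_that("batch scale factors are median-total ratios", {
  sf <- batchScaleFactors(makeBatchSet(c(100, 200, 400)))
  expect_equal(sf$scale_factor[match(c("B1", "B2", "B3"), sf$batch)],
               c(2, 1, 0.5))
  sf2 <- batchScaleFactors(makeBatchSet(c(100, 300)))
  expect_equal(sort(sf2$scale_factor), c(2 / 3, 2))   # even-count median = 200
  sf3 <- batchScaleFactors(makeBatchSet(c(7, 7, 7)))
  expect_equal(sf3$scale_factor, c(1, 1, 1))
})

test_that("batch normalization conserves the median batch total and runs once", {
  cs <- makeBatchSet(c(100, 200, 400))
  nb <- normaliseBatches(cs)
  totals <- tapply(cellMetrics(nb)$libSize, cellInfo(nb)$batch, sum)
  expect_equal(unname(as.numeric(totals)), c(200, 200, 200), tolerance = 1e-9)
  expect_equal(normState(nb), "batch_normalized")
  expect_error(normaliseBatches(nb), "raw")

  single <- newCellSet(tinyCounts(),
                       cellInfo = data.frame(batch = c("1", "1", "1"),
                                             row.names = c("c1", "c2", "c3")))
  expect_error(normaliseBatches(single), "nothing to normalize")

  zero <- makeBatchSet(c(100, 0))
  expect_error(normaliseBatches(zero), "zero total")
})

test_that("geometric mean ignores zeros and flags empty input", {
  expect_equal(geometricMeanNonzero(c(0, 2, 8)), 4)
  expect_true(is.na(geometricMeanNonzero(c(0, 0))))
  expect_equal(geometricMeanNonzero(5), 5)
})

test_that("RLE size factors match the hand-derived proportional-cell example", {
  m <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  sf <- rleSizeFactors(m)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(sf$n_genes_used, c(3L, 3L))

  one <- rleSizeFactors(matrix(c(3, 5), 2, 1,
                               dimnames = list(c("g1", "g2"), "c1")))
  expect_equal(one$size_factor, 1)
})

test_that("RLE handles zeros per the stated formula (brute-force cross-check)", {
  m <- matrix(c(4, 0,
                2, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  # brute force from the definition
  geo <- apply(m, 1, function(v) exp(mean(log(v[v > 0]))))
  expected <- sapply(seq_len(ncol(m)), function(j) {
    r <- m[, j] / geo
    median(r[m[, j] > 0])
  })
  sf <- rleSizeFactors(m)
  expect_equal(sf$size_factor, unname(expected), tolerance = 1e-12)
  # g1's geomean uses only its nonzero cell (value 4)
  expect_equal(geo[["g1"]], 4)
  expect_equal(sf$n_genes_used, c(2L, 1L))
})

test_that("RLE size factors are scale- and permutation-equivariant", {
  set.seed(21)
  m <- matrix(rpois(60, 5) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  base <- rleSizeFactors(m)$size_factor
  # factors are relative: scaling the whole matrix by c also scales every
  # geometric-mean reference by c and leaves the factors unchanged
  expect_equal(rleSizeFactors(m * 7)$size_factor, base, tolerance = 1e-12)

  # scaling one deep cell: its factor follows the scale up to the induced
  # drift of the geometric means (exact in the many-cell limit)
  m2 <- m; m2[, 3] <- m2[, 3] * 7
  expect_gt(rleSizeFactors(m2)$size_factor[3], 0.5 * 7 * base[3])

  pg <- sample(nrow(m)); pc <- sample(ncol(m))
  perm <- rleSizeFactors(m[pg, pc])
  expect_equal(perm$size_factor, base[pc], tolerance = 1e-12)
})

test_that("RLE normalization equalizes proportional cells and runs once", {
  m <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  cs <- newCellSet(m)
  nr <- normaliseByRLE(cs)
  nm <- as.matrix(counts(nr))
  expect_equal(unname(nm[, 1]), unname(nm[, 2]), tolerance = 1e-9)
  expect_equal(unname(nm[, 1]), c(2, 4, 8) * sqrt(2), tolerance = 1e-9)
  expect_equal(normState(nr), "rle_normalized")
  expect_error(normaliseByRLE(nr), "already")

  const <- newCellSet(matrix(3, 2, 4, dimnames = list(c("g1", "g2"),
                                                      paste0("c", 1:4))))
  cn <- normaliseByRLE(const)
  expect_equal(as.matrix(counts(cn)), as.matrix(counts(const)))

  empty <- matrix(c(1, 0, 0, 0), 2,
                  dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(rleSizeFactors(empty), "c2")
})

test_that("RLE after batch normalization is allowed and tracked", {
  cs <- randomCountSet(12, 10, seed = 22)
  nb <- normaliseBatches(cs)
  both <- normaliseByRLE(nb)
  expect_equal(normState(both), "rle_normalized")
  ops <- vapply(operationLog(both), `[[`, character(1), "operation")
  expect_equal(tail(ops, 2), c("normaliseBatches", "normaliseByRLE"))
})
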