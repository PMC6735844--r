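test_that("construction computes metrics and opens the log", {
  cs <- newCellSet(tinyCounts())
  expect_s4_class(cs, "CellSet")
  expect_equal(cellMetrics(cs)$libSize, c(1, 4, 2))
  expect_equal(cellMetrics(cs)$nGenesDetected, c(1, 1, 1))
  expect_equal(geneMetrics(cs)$totalCounts, c(3, 4))
  expect_equal(normState(cs), "raw")
  log <- operationLog(cs)
  expect_length(log, 1)
  expect_equal(log[[1]]$operation, "create")
})

test_that("construction rejects malformed input with precise errors", {
  m <- tinyCounts()
  expect_error(newCellSet(m, cellInfo = data.frame(batch = c("1", "2"))),
               "cell axis mismatch")
  expect_error(newCellSet(m, geneInfo = data.frame(sym = "a")),
               "gene axis mismatch")
  expect_error(newCellSet(m, controls = list(Mt = "geneX")), "geneX")
  bad <- m; bad[2, 3] <- -1
  expect_error(newCellSet(bad), "gene row 2, cell column 3")
  bad2 <- m; bad2[1, 1] <- NA
  expect_error(newCellSet(bad2), "negative or non-finite")
})

test_that("duplicate identifiers are deterministically de-duplicated", {
  m <- tinyCounts()
  rownames(m) <- c("dup", "dup")
  cs <- newCellSet(m)
  expect_equal(rownames(cs), c("dup", "dup.1"))
  expect_equal(as.character(geneInfo(cs)$originalId), c("dup", "dup"))
})

test_that("subsetCells keeps requested cells, recomputes metrics, logs removals", {
  cs <- randomCountSet(10, 20, seed = 4, controls = TRUE)
  all <- subsetCells(cs, colnames(cs))
  expect_equal(counts(all), counts(cs))
  expect_length(operationLog(all), length(operationLog(cs)) + 1)

  b1 <- subsetCells(cs, function(cd) cd$batch == "1")
  expect_true(all(cellInfo(b1)$batch == "1"))
  fresh <- computeGeneMetrics(counts(b1))
  expect_equal(geneMetrics(b1)$totalCounts, fresh$total_counts)
  expect_equal(geneMetrics(b1)$nCellsExpressing, fresh$n_cells_expressing)
  rec <- operationLog(b1)[[length(operationLog(b1))]]
  expect_setsEqual(rec$removed_cell_ids, setdiff(colnames(cs), colnames(b1)))

  expect_error(subsetCells(cs, function(cd) rep(FALSE, nrow(cd))),
               "all cells removed")
  expect_error(subsetCells(cs, "nonexistent"), "unknown cell id")
})

test_that("subsetGenes mirrors the cell axis and prunes control sets", {
  cs <- randomCountSet(10, 6, seed = 5, controls = TRUE)
  one <- subsetGenes(cs, rownames(cs)[3])
  expect_equal(nrow(one), 1)
  expect_equal(cellMetrics(one)$libSize,
               as.numeric(counts(cs)[3, ]))
  expect_length(controlGenes(one)$Mt, 0)
  rec <- operationLog(one)[[length(operationLog(one))]]
  expect_setsEqual(rec$removed_gene_ids, rownames(cs)[-3])
  expect_error(subsetGenes(cs, character(0)), "all genes removed")
})

test_that("excludeControlGenes removes exactly the named control sets", {
  m <- tinyCounts()
  cs <- newCellSet(m, controls = list(Mt = "g1", Rb = character(0)))
  ex <- excludeControlGenes(cs, "Mt")
  expect_equal(rownames(ex), "g2")
  expect_length(controlGenes(ex)$Mt, 0)
  ex2 <- excludeControlGenes(cs, c("Mt", "Rb"))  # empty Rb: no error
  expect_equal(rownames(ex2), "g2")
  expect_error(excludeControlGenes(cs, "Xx"), "unknown control")
})

test_that("metrics always match a from-scratch recomputation after any sequence", {
  cs <- randomCountSet(30, 40, seed = 6, controls = TRUE)
  cs <- subsetCells(cs, function(cd) cd$libSize > 0)
  cs <- filterLowAbundanceGenes(cs, 5)
  cs <- normaliseBatches(cs)
  cs <- normaliseByRLE(cs)
  cm <- computeCellMetrics(counts(cs), controlGenes(cs))
  expect_identical(cellMetrics(cs)$nGenesDetected, cm$n_genes_detected)
  expect_equal(cellMetrics(cs)$libSize, cm$library_size, tolerance = 1e-12)
  expect_equal(cellMetrics(cs)$pct_Mt, cm$pct_Mt, tolerance = 1e-12)
  gm <- computeGeneMetrics(counts(cs))
  expect_equal(geneMetrics(cs)$pctTotalExpression, gm$pct_total_expression,
               tolerance = 1e-12)
  expect_equal(sum(geneMetrics(cs)$pctTotalExpression), 100, tolerance = 1e-9)
})

test_that("replaying logged removals against the original reproduces the final set", {
  cs0 <- randomCountSet(25, 30, seed = 7, controls = TRUE)
  cs <- filterByOutliers(cs0)
  cs <- filterLowAbundanceGenes(cs, 10)
  cs <- subsetCells(cs, function(cd) cd$batch == "1")
  log <- operationLog(cs)
  genes <- rownames(cs0); cells <- colnames(cs0)
  for (rec in log[-1]) {
    genes <- setdiff(genes, rec$removed_gene_ids)
    cells <- setdiff(cells, rec$removed_cell_ids)
    expect_length(intersect(rec$removed_gene_ids, genes), 0)
    expect_length(intersect(rec$removed_cell_ids, cells), 0)
  }
  expect_identical(genes, rownames(cs))
  expect_identical(cells, colnames(cs))
  replay <- subsetCells(subsetGenes(cs0, genes), cells)
  expect_equal(counts(replay), counts(cs))
})

test_that("cell subsetting composes like set intersection", {
  cs <- randomCountSet(8, 20, seed = 8)
  A <- colnames(cs)[c(1:10, 15)]
  B <- colnames(cs)[5:20]
  # the second subset is expressed as a predicate: membership in B among
  # whatever cells remain
  ab <- subsetCells(subsetCells(cs, A), function(cd) rownames(cd) %in% B)
  direct <- subsetCells(cs, intersect(A, B))
  expect_identical(colnames(ab), colnames(direct))
  expect_equal(counts(ab), counts(direct))
})

test_that("bracket subsetting behaves like the explicit operations and logs once", {
  cs <- randomCountSet(8, 10, seed = 9, controls = TRUE)
  sub <- cs[rownames(cs)[1:4], 1:5]
  expect_equal(dim(sub), c(4L, 5L))
  expect_length(operationLog(sub), length(operationLog(cs)) + 1)
  expect_setsEqual(controlGenes(sub)$Mt,
                   intersect(controlGenes(cs)$Mt, rownames(sub)))
})
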