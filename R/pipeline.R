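# Ordered pipeline execution with on-disk outputs.

.STEP_ORDER <- c(filter = 1, normaliseBatches = 2, normaliseByRLE = 3,
                 excludeControls = 4, pca = 5, core = 6, de = 7)

#' Run an ordered analysis pipeline
#'
#' Executes a declarative pipeline configuration — input, then an ordered
#' list of steps — and writes all outputs as plain-text files. Step order
#' is validated *before* execution against the canonical ordering
#' (filter, batch normalization, RLE normalization, control exclusion,
#' PCA, CORE clustering, differential expression); out-of-order
#' configurations are refused up front. Given the same configuration and
#' seed, all written tables are byte-identical across runs.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{seed}{integer RNG seed for the whole run.}
#'     \item{input}{one of `list(simulate = simConfig(...))`,
#'       `list(bundle = dir)`, `list(dense = path)` or
#'       `list(mtx = dir)`. Dense/mtx inputs parse batch labels from the
#'       barcode suffix and detect Mt/Rb control genes by name.}
#'     \item{steps}{ordered list of `list(name = <step>, ...params)`.
#'       Step names as in the ordering above. The `filter` step applies
#'       outlier, control-percentage and gene-abundance filters in the
#'       canonical order with params `cellThreshold`, `controlThreshold`,
#'       `controlPct` (named list, e.g. `list(Mt = 20, Rb = 50)`),
#'       `genePct`. The `de` step takes `group`, `conditionA`,
#'       `conditionB` (or `each = TRUE` for every cluster vs the rest),
#'       `correction`, `alpha`, `minAbsLog2FC`, `delta`.}
#'   }
#' @param outDir output directory; receives the final bundle (`bundle/`),
#'   `clusters.tsv`, `stability.tsv`, `scree.tsv`, `sizefactors.tsv`,
#'   `de_<a>_vs_<b>.tsv`, `filter_report.json`, `pipeline_log.jsonl` and
#'   `report.md` as applicable.
#' @return invisibly, a list with the final `set` and named intermediate
#'   `results`.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$steps))
  stepNames <- vapply(config$steps, `[[`, character(1), "name")
  unknown <- setdiff(stepNames, names(.STEP_ORDER))
  if (length(unknown))
    stop(sprintf("unknown step(s): %s", paste(unknown, collapse = ", ")))
  ranks <- .STEP_ORDER[stepNames]
  if (any(diff(ranks) <= 0))
    stop(sprintf("steps out of order: '%s' cannot follow '%s'",
                 stepNames[which(diff(ranks) <= 0)[1L] + 1L],
                 stepNames[which(diff(ranks) <= 0)[1L]]))

  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  runLog <- file.path(outDir, "pipeline_log.jsonl")
  cat(NULL, file = runLog)
  logStep <- function(name, info = list()) {
    cat(jsonlite::toJSON(c(list(step = name), info), auto_unbox = TRUE),
        "\n", sep = "", file = runLog, append = TRUE)
  }

  x <- .loadPipelineInput(config$input)
  logStep("input", list(genes = nrow(x), cells = ncol(x)))
  results <- list()

  for (step in config$steps) {
    nm <- step$name
    before <- dim(x)
    x <- switch(nm,
      filter = {
        x2 <- filterByOutliers(x,
                cellThreshold = step$cellThreshold %||% 3,
                controlThreshold = step$controlThreshold %||% 3)
        ctl <- step$controlPct %||% list(Mt = 20, Rb = 50)
        for (cn in names(ctl))
          if (cn %in% names(controlGenes(x2)))
            x2 <- filterByControl(x2, cn, ctl[[cn]])
        filterLowAbundanceGenes(x2, step$genePct %||% 0.1)
      },
      normaliseBatches = normaliseBatches(x),
      normaliseByRLE = {
        x2 <- normaliseByRLE(x)
        .writeTSV(data.frame(cell_id = colnames(x2),
                             size_factor = colData(x2)$sizeFactor),
                  file.path(outDir, "sizefactors.tsv"))
        x2
      },
      excludeControls = excludeControlGenes(
        x, step$control %||% names(controlGenes(x))),
      pca = {
        x2 <- runPCA(x, ngenes = step$ngenes %||% 1500,
                     scaling = step$scaling %||% TRUE,
                     k = step$k %||% min(50, ncol(x) - 1L, nrow(x)))
        results$pca <- pcaResult(x2)
        .writeTSV(plotPCAVariance(results$pca)$data,
                  file.path(outDir, "scree.tsv"))
        x2
      },
      core = {
        x2 <- runCORE(x, dims = step$dims %||% 20, nres = step$nres %||% 40,
                      removeOutliers = step$removeOutliers %||% TRUE,
                      conservative = step$conservative %||% FALSE,
                      minClusterSize = step$minClusterSize %||% 3)
        results$core <- metadata(x2)$core
        .writeTSV(coreStabilityTable(results$core),
                  file.path(outDir, "stability.tsv"))
        .writeTSV(data.frame(cell_id = colnames(x2),
                             cluster = colData(x2)$cluster),
                  file.path(outDir, "clusters.tsv"))
        x2
      },
      de = {
        results$de <- .runDEStep(x, step, outDir)
        x
      })
    logStep(nm, list(genes_before = before[1L], cells_before = before[2L],
                     genes_after = nrow(x), cells_after = ncol(x)))
  }

  if ("filter" %in% stepNames) {
    recs <- operationLog(x)
    filt <- Filter(function(r) startsWith(r$operation, "filter"), recs)
    rep <- lapply(filt, function(r)
      list(operation = r$operation, params = r$params,
           cells_removed = length(r$removed_cell_ids),
           genes_removed = length(r$removed_gene_ids)))
    jsonlite::write_json(rep, file.path(outDir, "filter_report.json"),
                         auto_unbox = TRUE)
  }

  writeBundle(x, file.path(outDir, "bundle"))
  .writePipelineReport(x, results, outDir)
  invisible(list(set = x, results = results, dir = outDir))
}

.loadPipelineInput <- function(input) {
  if (!is.null(input$simulate)) {
    return(simulateCellSet(input$simulate)$set)
  }
  if (!is.null(input$bundle)) return(readBundle(input$bundle))
  raw <- if (!is.null(input$dense)) {
    readDenseCounts(input$dense, input$delimiter %||% "\t")
  } else if (!is.null(input$mtx)) {
    readMTXBundle(input$mtx)
  } else stop("input must name one of: simulate, bundle, dense, mtx")
  batch <- parseBatchFromBarcode(raw$cell_ids,
                                 separator = input$batchSeparator %||% ".",
                                 fallback = input$batchFallback %||% "1")
  controls <- list()
  mt <- grep("^Mt-", raw$gene_ids, ignore.case = TRUE, value = TRUE)
  rb <- grep("^Rps|^Rpl", raw$gene_ids, ignore.case = TRUE, value = TRUE)
  if (length(mt)) controls$Mt <- mt
  if (length(rb)) controls$Rb <- rb
  ci <- data.frame(cell_barcode = raw$cell_ids, batch = batch,
                   row.names = raw$cell_ids, stringsAsFactors = FALSE)
  newCellSet(raw$counts, cellInfo = ci, controls = controls)
}

.runDEStep <- function(x, step, outDir) {
  group <- step$group %||% "cluster"
  correction <- step$correction %||% "bonferroni"
  delta <- step$delta %||% 1
  alpha <- step$alpha %||% 0.05
  minFC <- step$minAbsLog2FC %||% 0
  pairs <- if (isTRUE(step$each)) {
    labs <- sort(unique(as.character(colData(x)[[group]])))
    lapply(labs, function(a) list(a = a, b = setdiff(labs, a)))
  } else {
    list(list(a = step$conditionA, b = step$conditionB))
  }
  out <- list()
  for (pr in pairs) {
    tab <- runDiffExpression(x, group, pr$a, pr$b,
                             correction = correction, delta = delta)
    tab$significant <- !is.na(tab$adjusted_p) & tab$adjusted_p < alpha &
      abs(tab$log2_fold_change) > minFC
    key <- sprintf("%s_vs_%s", paste(pr$a, collapse = "+"),
                   paste(pr$b, collapse = "+"))
    .writeTSV(tab, file.path(outDir, sprintf("de_%s.tsv", key)))
    out[[key]] <- tab
  }
  out
}

.writePipelineReport <- function(x, results, outDir) {
  lines <- c("# Pipeline report", "",
             sprintf("Final data set: %d genes x %d cells (%s).",
                     nrow(x), ncol(x), normState(x)),
             "", "## Operations")
  for (r in operationLog(x))
    lines <- c(lines, sprintf(
      "- %s: %dx%d -> %dx%d (removed %d cells, %d genes)",
      r$operation, r$before["genes"], r$before["cells"],
      r$after["genes"], r$after["cells"],
      length(r$removed_cell_ids), length(r$removed_gene_ids)))
  if (!is.null(results$pca))
    lines <- c(lines, "", sprintf(
      "PCA: first 10 components explain %.2f%% of the variance.",
      varianceExplained(results$pca,
                        min(10, length(results$pca@varianceExplained)))))
  if (!is.null(results$core)) {
    k <- results$core@nClusters[results$core@selectedWindow]
    sizes <- sort(table(results$core@stableLabels), decreasing = TRUE)
    lines <- c(lines, sprintf(
      "CORE: %d stable cluster%s (sizes %s) selected at window %d of %d.",
      k, if (k == 1) "" else "s", paste(as.integer(sizes), collapse = ", "),
      results$core@selectedWindow, length(results$core@windows)))
  }
  if (!is.null(results$de))
    for (key in names(results$de))
      lines <- c(lines, sprintf("DE %s: %d significant gene(s).",
                                key, sum(results$de[[key]]$significant)))
  writeLines(lines, file.path(outDir, "report.md"))
}
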