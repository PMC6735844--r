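# Count-matrix readers and the lossless on-disk bundle.
#
# A bundle is a directory holding:
#   matrix.mtx     Matrix Market coordinate (1-based on disk)
#   genes.tsv      gene id <TAB> gene name (10x-style; name = id if absent)
#   barcodes.tsv   one cell barcode per line
#   cell_info.tsv, gene_info.tsv   metadata + current QC metrics
#   controls.json  control sets, dropped members, excluded names
#   log.jsonl      one operation record per line
#   reduced_<name>.tsv, clusters.tsv  (optional)
#   manifest.json  format version + normalization state

.BUNDLE_VERSION <- "1"

#' Read a dense count matrix from a delimited text file
#'
#' The first row is a header of cell barcodes; the first column of each
#' subsequent row is the gene id. Values may be real (post-normalization
#' matrices). Malformed input is reported precisely: ragged rows by line
#' number, non-numeric values by row/column coordinates.
#'
#' @param path file path (plain or gzip, by extension).
#' @param delimiter field separator (default tab).
#' @return list with `counts` (sparse genes x cells), `gene_ids`,
#'   `cell_ids`.
#' @export
readDenseCounts <- function(path, delimiter = "\t") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("file must contain a header row and at least one gene row")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading gene-id column label
  widths <- lengths(fields[-1L])
  nCells <- widths[1L] - 1L
  if (length(header) == nCells + 1L) header <- header[-1L]
  if (length(header) != nCells)
    stop(sprintf("header has %d cell barcodes but row 2 has %d value columns",
                 length(header), nCells))
  ragged <- which(widths != nCells + 1L)
  if (length(ragged))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 ragged[1L] + 1L, nCells + 1L, widths[ragged[1L]]))
  geneIds <- vapply(fields[-1L], `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(fields[-1L], function(f) as.numeric(f[-1L]), numeric(nCells)))
  vals <- if (nCells == 1L) matrix(vals, nrow = 1L) else t(vals)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value at gene row %d (line %d), cell column %d",
                 bad[1L, 1L], bad[1L, 1L] + 1L, bad[1L, 2L]))
  dimnames(vals) <- list(geneIds, header)
  list(counts = .sparsify(vals), gene_ids = geneIds, cell_ids = header)
}

#' Parse batch labels out of cell barcodes
#'
#' Returns the token after the *first* occurrence of `separator` in each
#' barcode: `"AAACATACG.1" -> "1"` with `"."`, `"AAAC-1" -> "1"` with
#' `"-"` (the 10x convention).
#'
#' @param cellIds character vector of barcodes.
#' @param separator single character separating barcode and batch suffix
#'   (default `"."`).
#' @param fallback optional single batch label used for barcodes without
#'   the separator; without it such barcodes are an error.
#' @return character vector of batch labels.
#' @export
parseBatchFromBarcode <- function(cellIds, separator = ".", fallback = NULL) {
  pos <- regexpr(separator, cellIds, fixed = TRUE)
  missing <- pos < 0
  if (any(missing) && is.null(fallback))
    stop(sprintf("barcode(s) without separator '%s': %s", separator,
                 paste(utils::head(cellIds[missing], 5), collapse = ", ")))
  out <- ifelse(missing, fallback %||% NA_character_,
                substr(cellIds, pos + 1L, nchar(cellIds)))
  as.character(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 10x-style Matrix Market triplet bundle
#'
#' Expects `matrix.mtx[.gz]`, `genes.tsv[.gz]` (one or two columns:
#' id, name) and `barcodes.tsv[.gz]` in `dir`. Duplicate coordinate
#' triplets are summed with a warning.
#'
#' @param dir directory path.
#' @return list with `counts` (sparse genes x cells), `gene_ids`,
#'   `cell_ids`, `gene_names`.
#' @export
readMTXBundle <- function(dir) {
  f <- function(base) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(base, ext))
      if (file.exists(p)) return(p)
    }
    stop(sprintf("missing %s in %s", base, dir))
  }
  m <- Matrix::readMM(f("matrix.mtx"))
  genes <- utils::read.table(f("genes.tsv"), sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  barcodes <- readLines(f("barcodes.tsv"))
  if (nrow(genes) != nrow(m))
    stop(sprintf("dimension mismatch: matrix.mtx declares %d genes but genes.tsv has %d lines",
                 nrow(m), nrow(genes)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("dimension mismatch: matrix.mtx declares %d cells but barcodes.tsv has %d lines",
                 ncol(m), length(barcodes)))
  nTriplets <- length(m@x)
  mc <- .sparsify(m)                 # sums duplicate triplets
  if (length(mc@x) < nTriplets)
    warning("duplicate coordinate triplets in matrix.mtx were summed")
  geneIds <- genes[[1L]]
  geneNames <- if (ncol(genes) >= 2L) genes[[2L]] else geneIds
  dimnames(mc) <- list(geneIds, barcodes)
  list(counts = mc, gene_ids = geneIds, cell_ids = barcodes,
       gene_names = geneNames)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

#' Write a CellSet to an on-disk bundle
#'
#' Serializes the full container — counts, metadata, control sets,
#' operation log, reduced dimensions and cluster labels — to a directory
#' of plain-text files. [readBundle()] restores it losslessly (counts
#' exactly for integers, to full double precision otherwise).
#'
#' @param x a [CellSet-class].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(x, dir) {
  .assertCellSet(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- assay(x, "counts")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(paste(rownames(x), rownames(x), sep = "\t"),
             file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))

  ci <- as.data.frame(colData(x))
  .writeTSV(cbind(cell_id = rownames(ci), ci), file.path(dir, "cell_info.tsv"))
  ri <- as.data.frame(rowData(x))
  .writeTSV(cbind(gene_id = rownames(ri), ri), file.path(dir, "gene_info.tsv"))

  jsonlite::write_json(
    list(controls = x@controls, dropped = x@controlsDropped,
         excluded = x@excludedControls),
    file.path(dir, "controls.json"), auto_unbox = FALSE, digits = NA)

  logLines <- vapply(x@opLog, function(rec)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1))
  writeLines(logLines, file.path(dir, "log.jsonl"))

  for (nm in reducedDimNames(x)) {
    rd <- as.data.frame(reducedDim(x, nm))
    .writeTSV(cbind(cell_id = colnames(x), format(rd, digits = 17, trim = TRUE,
                                                  scientific = NA)),
              file.path(dir, paste0("reduced_", nm, ".tsv")))
  }
  if ("cluster" %in% colnames(colData(x)))
    .writeTSV(data.frame(cell_id = colnames(x),
                         cluster = colData(x)$cluster),
              file.path(dir, "clusters.tsv"))

  colClass <- function(df) vapply(as.list(df), function(v) class(v)[1], character(1))
  jsonlite::write_json(
    list(format_version = .BUNDLE_VERSION, norm_state = x@normState,
         n_genes = nrow(x), n_cells = ncol(x),
         cell_info_classes = as.list(colClass(colData(x))),
         gene_info_classes = as.list(colClass(rowData(x)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a CellSet bundle
#'
#' Inverse of [writeBundle()].
#'
#' @param dir bundle directory.
#' @return the restored [CellSet-class].
#' @export
readBundle <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    stop(sprintf("missing manifest.json in %s: not a bundle", dir))
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), .BUNDLE_VERSION))
    stop(sprintf("unsupported bundle format version '%s'", manifest$format_version))

  raw <- readMTXBundle(dir)
  m <- raw$counts

  classesOf <- function(key) {
    cl <- unlist(manifest[[key]])
    if (is.null(cl)) return(character(0))
    cl[!cl %in% c("character", "integer", "numeric", "logical")] <- "character"
    cl
  }
  ci <- utils::read.table(file.path(dir, "cell_info.tsv"), sep = "\t",
                          header = TRUE, quote = "", stringsAsFactors = FALSE,
                          colClasses = c(cell_id = "character", classesOf("cell_info_classes")),
                          check.names = FALSE)
  ri <- utils::read.table(file.path(dir, "gene_info.tsv"), sep = "\t",
                          header = TRUE, quote = "", stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character", classesOf("gene_info_classes")),
                          check.names = FALSE)
  stopifnot(identical(ci$cell_id, raw$cell_ids),
            identical(ri$gene_id, raw$gene_ids))

  ctl <- jsonlite::read_json(file.path(dir, "controls.json"), simplifyVector = TRUE)
  toCharList <- function(l) lapply(l, as.character)
  controls <- toCharList(as.list(ctl$controls))

  cd <- DataFrame(ci[, -1L, drop = FALSE], row.names = raw$cell_ids)
  rd <- DataFrame(ri[, -1L, drop = FALSE], row.names = raw$gene_ids)
  sce <- SingleCellExperiment(assays = list(counts = m), colData = cd, rowData = rd)
  x <- methods::new("CellSet", sce,
                    controls = controls,
                    controlsDropped = toCharList(as.list(ctl$dropped)),
                    excludedControls = as.character(ctl$excluded),
                    opLog = list(), normState = as.character(manifest$norm_state))

  logLines <- readLines(file.path(dir, "log.jsonl"))
  x@opLog <- lapply(logLines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    rec$removed_cell_ids <- as.character(rec$removed_cell_ids)
    rec$removed_gene_ids <- as.character(rec$removed_gene_ids)
    rec$params <- as.list(rec$params)
    rec$before <- unlist(rec$before); rec$after <- unlist(rec$after)
    rec
  })

  for (f in list.files(dir, pattern = "^reduced_.*\\.tsv$")) {
    nm <- sub("^reduced_(.*)\\.tsv$", "\\1", f)
    tab <- utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                             quote = "", colClasses = c(cell_id = "character"),
                             check.names = FALSE)
    sc <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(sc) <- tab$cell_id
    reducedDim(x, nm) <- sc
  }
  .recomputeMetrics(x)
}
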