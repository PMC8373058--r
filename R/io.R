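#' Read an expression matrix into an ScBatch
#'
#' Supports two on-disk encodings:
#' \describe{
#'   \item{delimited}{UTF-8 TSV/CSV, first row = gene identifiers, first
#'     column = cell identifiers, remaining fields numeric (cells x genes on
#'     disk).}
#'   \item{matrix_market}{coordinate `.mtx` with `<prefix>.features.tsv` and
#'     `<prefix>.barcodes.tsv` sidecars (one identifier per line),
#'     genes-as-rows convention; orientation is auto-detected from the
#'     sidecar lengths and transposed if needed.}
#' }
#' Duplicate gene identifiers are collapsed by summing their counts.
#'
#' @param path path to the matrix file.
#' @param format `"auto"` (by extension), `"delimited"` or `"matrix_market"`.
#' @param labelsPath optional path to a two-column TSV (cell_id, cell_type;
#'   header optional) assigning every cell a label.
#' @param name batch identifier; defaults to the file name stem.
#' @return an [ScBatch-class] with raw counts.
#' @export
readExpressionMatrix <- function(path,
                                 format = c("auto", "delimited",
                                            "matrix_market"),
                                 labelsPath = NULL, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopUsage("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "matrix_market" else "delimited"
  if (is.null(name))
    name <- sub("\\.(counts\\.)?(tsv|csv|txt|mtx)$", "", basename(path))
  counts <- switch(format,
    delimited = .readDelimited(path),
    matrix_market = .readMatrixMarket(path))
  counts <- .collapseDuplicateGenes(counts)
  labels <- NULL
  if (!is.null(labelsPath)) {
    lab <- readCellTypeLabels(labelsPath)
    labels <- .matchLabels(lab, colnames(counts), path)
  }
  ScBatch(counts, cellTypes = labels, name = name)
}

# cells x genes on disk -> genes x cells sparse matrix. The header is read
# separately so duplicated gene identifiers reach the collapse step intact
# (fread would silently uniquify them).
.readDelimited <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  genes <- strsplit(hdr, sep, fixed = TRUE)[[1]][-1]
  if (!length(genes))
    .stopUsage("malformed delimited file %s: no gene columns in header", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, skip = 1, sep = sep,
                      data.table = FALSE),
    error = function(e) .stopUsage("malformed delimited file %s: %s",
                                   path, conditionMessage(e)))
  if (ncol(dt) != length(genes) + 1)
    .stopUsage("malformed delimited file %s: %d header fields but %d columns",
               path, length(genes) + 1, ncol(dt))
  cells <- as.character(dt[[1]])
  num <- dt[, -1, drop = FALSE]
  bad <- which(!vapply(num, is.numeric, logical(1)))
  if (length(bad))
    .stopUsage("malformed delimited file %s: non-numeric values in column %d",
               path, bad[1] + 1L)
  m <- t(as.matrix(num))           # genes x cells
  dimnames(m) <- list(genes, cells)
  Matrix::Matrix(m, sparse = TRUE)
}

.readSidecar <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  # CellRanger-style features files may carry extra tab-separated columns
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

.readMatrixMarket <- function(path) {
  prefix <- sub("\\.mtx$", "", path)
  fFeat <- paste0(prefix, ".features.tsv")
  fBar <- paste0(prefix, ".barcodes.tsv")
  if (!file.exists(fFeat))
    fFeat <- file.path(dirname(path), "features.tsv")
  if (!file.exists(fBar))
    fBar <- file.path(dirname(path), "barcodes.tsv")
  if (!file.exists(fFeat) || !file.exists(fBar))
    .stopUsage("missing features/barcodes sidecars for %s", path)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) .stopUsage("malformed MatrixMarket file %s: %s",
                                               path, conditionMessage(e)))
  feats <- .readSidecar(fFeat)
  bars <- .readSidecar(fBar)
  if (nrow(m) == length(feats) && ncol(m) == length(bars)) {
    # genes-as-rows: keep
  } else if (nrow(m) == length(bars) && ncol(m) == length(feats)) {
    m <- Matrix::t(m)
  } else {
    .stopUsage(
      "sidecar lengths (%d features, %d barcodes) do not match matrix %d x %d",
      length(feats), length(bars), nrow(m), ncol(m))
  }
  dimnames(m) <- list(feats, bars)
  methods::as(m, "CsparseMatrix")
}

.collapseDuplicateGenes <- function(m) {
  g <- rownames(m)
  if (!anyDuplicated(g)) return(m)
  keep <- unique(g)
  grp <- match(g, keep)
  agg <- Matrix::sparseMatrix(i = grp, j = seq_along(g), x = 1,
                              dims = c(length(keep), length(g)))
  out <- agg %*% m
  dimnames(out) <- list(keep, colnames(m))
  methods::as(out, "CsparseMatrix")
}

#' Read a two-column cell-type label table
#'
#' TSV with columns (cell_id, cell_type); a header line is detected and
#' skipped when its fields look like column names.
#'
#' @param path path to the label TSV.
#' @return data.frame with columns `cell_id`, `cell_type`.
#' @export
readCellTypeLabels <- function(path) {
  if (!file.exists(path)) .stopUsage("label file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE, sep = "\t")
  if (ncol(dt) != 2)
    .stopUsage("label table %s must have exactly 2 columns, found %d",
               path, ncol(dt))
  headerish <- c("cell_id", "cellid", "cell", "barcode", "cell_type",
                 "celltype", "label", "type")
  if (tolower(dt[1, 1]) %in% headerish || tolower(dt[1, 2]) %in% headerish)
    dt <- dt[-1, , drop = FALSE]
  data.frame(cell_id = as.character(dt[[1]]),
             cell_type = as.character(dt[[2]]),
             stringsAsFactors = FALSE)
}

.matchLabels <- function(lab, cells, path) {
  if (anyDuplicated(lab$cell_id))
    .stopUsage("label table for %s lists some cells more than once", path)
  idx <- match(cells, lab$cell_id)
  if (anyNA(idx))
    .stopUsage("label table for %s is missing %d cell(s), e.g. '%s'",
               path, sum(is.na(idx)), cells[which(is.na(idx))[1]])
  lab$cell_type[idx]
}

#' Write a batch to disk
#'
#' Writes the raw counts (and labels when present) in one of the two
#' encodings understood by [readExpressionMatrix()]: `<name>.counts.tsv`
#' (+ `<name>.labels.tsv`) or `<name>.mtx` with feature/barcode sidecars.
#'
#' @param x an [ScBatch-class] with raw counts.
#' @param dir output directory (created if needed).
#' @param format `"delimited"` or `"matrix_market"`.
#' @return invisibly, the path of the matrix file written.
#' @export
writeBatch <- function(x, dir, format = c("delimited", "matrix_market")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- batchName(x)
  cts <- assay(x, "counts")
  if (format == "delimited") {
    path <- file.path(dir, paste0(nm, ".counts.tsv"))
    dense <- as.matrix(Matrix::t(cts))   # cells x genes on disk
    dt <- data.table::data.table(cell_id = rownames(dense))
    for (j in seq_len(ncol(dense))) dt[[colnames(dense)[j]]] <- dense[, j]
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    path <- file.path(dir, paste0(nm, ".mtx"))
    Matrix::writeMM(methods::as(cts, "CsparseMatrix"), path)
    writeLines(rownames(x), file.path(dir, paste0(nm, ".features.tsv")))
    writeLines(colnames(x), file.path(dir, paste0(nm, ".barcodes.tsv")))
  }
  ct <- cellTypes(x)
  if (!is.null(ct)) {
    data.table::fwrite(
      data.table::data.table(cell_id = colnames(x), cell_type = ct),
      file.path(dir, paste0(nm, ".labels.tsv")), sep = "\t")
  }
  invisible(path)
}
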