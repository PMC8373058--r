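#' Cell quality-control thresholds
#'
#' Default thresholds follow common scRNA-seq practice: a cell is kept only
#' if it detects more than 500 genes, carries more than 1500 UMIs, and has a
#' mitochondrial count fraction below 10%. All three inequalities are
#' strict, so boundary values fail. Mitochondrial genes are recognized by a
#' case-insensitive identifier prefix (default `"MT-"`).
#'
#' @param minGenesDetected strict lower bound on the number of genes with a
#'   nonzero count.
#' @param minUMI strict lower bound on the cell's total count.
#' @param maxMitoFraction strict upper bound on the mitochondrial count
#'   fraction, in `[0, 1]`.
#' @param mitoPrefix identifier prefix marking mitochondrial genes.
#' @return a classed list of thresholds for [qcFilter()].
#' @export
qcThresholds <- function(minGenesDetected = 500, minUMI = 1500,
                         maxMitoFraction = 0.10, mitoPrefix = "MT-") {
  thr <- list(
    minGenesDetected = .checkCount(minGenesDetected, "minGenesDetected"),
    minUMI = .checkCount(minUMI, "minUMI"),
    maxMitoFraction = .checkScalar(maxMitoFraction, "maxMitoFraction", 0, 1),
    mitoPrefix = as.character(mitoPrefix))
  class(thr) <- "qcThresholds"
  thr
}

#' Filter low-quality cells
#'
#' Retains only cells with (number of detected genes) > `minGenesDetected`,
#' total counts > `minUMI`, and mitochondrial fraction < `maxMitoFraction`
#' (all strict). Operates on raw counts; apply before [logNormalize()].
#' Idempotent.
#'
#' @param x an [ScBatch-class] with raw counts.
#' @param thresholds a [qcThresholds()] list.
#' @param ... unused.
#' @return the filtered [ScBatch-class].
#' @rdname qcFilter
#' @export
setMethod("qcFilter", "ScBatch", function(x, thresholds = qcThresholds(), ...) {
  if (isNormalized(x))
    .stopUsage("qcFilter() operates on raw counts; '%s' is already normalized",
               batchName(x))
  cts <- assay(x, "counts")
  detected <- Matrix::colSums(cts > 0)
  total <- Matrix::colSums(cts)
  mito <- startsWith(toupper(rownames(x)), toupper(thresholds$mitoPrefix))
  mitoFrac <- if (any(mito)) {
    mf <- Matrix::colSums(cts[mito, , drop = FALSE])
    ifelse(total > 0, mf / total, 0)
  } else rep(0, ncol(x))
  keep <- detected > thresholds$minGenesDetected &
    total > thresholds$minUMI &
    mitoFrac < thresholds$maxMitoFraction
  if (!any(keep))
    .stopRuntime("qcFilter() removed every cell of '%s'", batchName(x))
  x[, keep]
})

#' Drop rare cell types
#'
#' Removes every cell whose type has fewer than `minCells` cells in the
#' batch (strict: a type with exactly `minCells` cells is retained). Rare
#' types carry too little information to define a reliable centroid.
#' Idempotent.
#'
#' @param x a labeled [ScBatch-class].
#' @param minCells minimum number of cells a type must have to survive.
#' @return the filtered [ScBatch-class].
#' @rdname filterRareTypes
#' @export
setMethod("filterRareTypes", "ScBatch", function(x, minCells = 10) {
  ct <- cellTypes(x)
  if (is.null(ct))
    .stopUsage("filterRareTypes() requires cell-type labels ('%s' has none)",
               batchName(x))
  minCells <- .checkCount(minCells, "minCells", min = 1)
  tab <- table(ct)
  keepTypes <- names(tab)[tab >= minCells]
  if (!length(keepTypes))
    .stopRuntime("no cell type of '%s' has >= %d cells", batchName(x), minCells)
  x[, ct %in% keepTypes]
})

#' Library-size log-normalization
#'
#' Scales each cell's counts to a fixed total (default 10 000) and applies
#' the natural log of (value + 1). Adds a `logcounts` assay and flags the
#' batch as normalized; the `counts` assay is kept. After normalization,
#' `sum(exp(v) - 1)` over a cell's genes equals `scale` exactly (up to
#' floating point).
#'
#' @param x an [ScBatch-class] with raw counts.
#' @param scale per-cell count total before the log transform.
#' @return the normalized [ScBatch-class].
#' @rdname logNormalize
#' @export
setMethod("logNormalize", "ScBatch", function(x, scale = 10000) {
  if (isNormalized(x))
    .stopUsage("'%s' is already normalized", batchName(x))
  scale <- .checkScalar(scale, "scale", 0, Inf, strict_lower = TRUE)
  cts <- assay(x, "counts")
  total <- Matrix::colSums(cts)
  if (any(total == 0))
    .stopRuntime("'%s' contains %d cell(s) with zero total counts; apply qcFilter() first",
                 batchName(x), sum(total == 0))
  scaled <- if (methods::is(cts, "sparseMatrix")) {
    cts %*% Matrix::Diagonal(x = scale / total)
  } else {
    sweep(cts, 2, scale / total, "*")
  }
  lg <- log1p(scaled)
  dimnames(lg) <- dimnames(cts)
  assay(x, "logcounts") <- lg
  metadata(x)$normalized <- TRUE
  methods::validObject(x)
  x
})

#' Gene union across references
#'
#' The shared input feature space: the union of all reference gene
#' identifiers, lexicographically sorted (byte order) so the feature order
#' is deterministic.
#'
#' @param refs a list of [ScBatch-class] objects (or a single one).
#' @return character vector of unique, sorted gene identifiers.
#' @export
buildGeneUnion <- function(refs) {
  if (methods::is(refs, "ScBatch")) refs <- list(refs)
  if (!length(refs)) .stopUsage("buildGeneUnion() needs at least one reference")
  .lexSort(unique(unlist(lapply(refs, rownames), use.names = FALSE)))
}

#' Align a batch to the gene union
#'
#' Reorders the gene dimension to exactly the union order: genes absent
#' from the batch become all-zero rows, genes not in the union are dropped,
#' and every retained value is preserved exactly. Idempotent.
#'
#' @param x a normalized [ScBatch-class].
#' @param union character vector from [buildGeneUnion()].
#' @return the aligned [ScBatch-class].
#' @rdname alignToUnion
#' @export
setMethod("alignToUnion", "ScBatch", function(x, union) {
  if (!isNormalized(x))
    .stopUsage("alignToUnion() expects a normalized batch; run logNormalize() first")
  if (!length(union) || anyDuplicated(union))
    .stopUsage("'union' must be a non-empty set of unique gene identifiers")
  if (identical(rownames(x), union)) return(x)
  idx <- match(union, rownames(x))
  present <- !is.na(idx)
  remap <- function(m) {
    out <- Matrix::Matrix(0, length(union), ncol(m), sparse = TRUE)
    out[present, ] <- m[idx[present], , drop = FALSE]
    dimnames(out) <- list(union, colnames(m))
    methods::as(out, "CsparseMatrix")
  }
  newAssays <- lapply(assayNames(x), function(a) remap(assay(x, a)))
  names(newAssays) <- assayNames(x)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = newAssays, colData = colData(x))
  metadata(sce) <- metadata(x)
  methods::new("ScBatch", sce)
})

#' Full reference preprocessing pipeline
#'
#' Applies, in order: cell QC ([qcFilter()], unless `qc = FALSE`), rare-type
#' filtering ([filterRareTypes()]), log-normalization ([logNormalize()]),
#' then computes the gene union over all surviving references and aligns
#' every reference to it.
#'
#' @param refs list of labeled [ScBatch-class] objects with raw counts.
#' @param thresholds [qcThresholds()] for the QC step.
#' @param minCells rare-type cutoff, see [filterRareTypes()].
#' @param scale normalization total, see [logNormalize()].
#' @param qc apply cell QC to the references (default TRUE).
#' @return list with elements `refs` (aligned batches) and `geneUnion`.
#' @export
preprocessReferences <- function(refs, thresholds = qcThresholds(),
                                 minCells = 10, scale = 10000, qc = TRUE) {
  if (methods::is(refs, "ScBatch")) refs <- list(refs)
  if (!length(refs)) .stopUsage("at least one reference is required")
  refs <- lapply(refs, function(r) {
    if (qc) r <- qcFilter(r, thresholds)
    r <- filterRareTypes(r, minCells)
    logNormalize(r, scale)
  })
  union <- buildGeneUnion(refs)
  refs <- lapply(refs, alignToUnion, union = union)
  list(refs = refs, geneUnion = union)
}

#' Prepare a query batch for assignment
#'
#' Optional QC, then log-normalization and alignment to the model's frozen
#' gene union (query-only genes are dropped; union genes missing from the
#' query are zero-filled). Warns prominently when the query shares no genes
#' with the union.
#'
#' @param query an [ScBatch-class] (raw counts or already normalized).
#' @param union the training gene union.
#' @param qc apply [qcFilter()] to the query (optional, default FALSE).
#' @param thresholds thresholds when `qc = TRUE`.
#' @param scale normalization total.
#' @return the aligned, normalized query [ScBatch-class].
#' @export
prepareQuery <- function(query, union, qc = FALSE,
                         thresholds = qcThresholds(), scale = 10000) {
  if (!isNormalized(query)) {
    if (qc) query <- qcFilter(query, thresholds)
    query <- logNormalize(query, scale)
  }
  overlap <- sum(rownames(query) %in% union)
  if (overlap == 0)
    warning("query '", batchName(query),
            "' shares no genes with the training gene union; ",
            "all inputs to the network will be zero", call. = FALSE)
  alignToUnion(query, union)
}
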