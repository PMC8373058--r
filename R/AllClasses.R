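#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' ScBatch: one expression batch (reference or query)
#'
#' An `ScBatch` is a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#' holding one scRNA-seq dataset: a `counts` assay (genes as rows, cells as
#' columns, raw non-negative integers), optionally a `logcounts` assay after
#' [logNormalize()], an optional `cellType` column in `colData` for labeled
#' references, and two metadata fields: `name` (batch identifier) and
#' `normalized` (logical).
#'
#' Gene and cell identifiers (dimnames) must be unique. Raw counts must be
#' integer-valued; duplicate gene identifiers are collapsed by summation at
#' read time by [readExpressionMatrix()].
#'
#' @seealso [readExpressionMatrix()], [qcFilter()], [logNormalize()]
#' @export
setClass("ScBatch", contains = "SingleCellExperiment")

setValidity("ScBatch", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object))
    msgs <- c(msgs, "an ScBatch requires a 'counts' assay")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msgs <- c(msgs, "gene identifiers must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msgs <- c(msgs, "cell identifiers must be present and unique")
  if (is.null(metadata(object)$name))
    msgs <- c(msgs, "metadata 'name' is required")
  norm <- isTRUE(metadata(object)$normalized)
  cts <- assay(object, "counts")
  mn <- suppressWarnings(min(cts))
  if (is.finite(mn) && mn < 0)
    msgs <- c(msgs, "counts must be non-negative")
  if (!norm && ncol(object) > 0) {
    v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.numeric(cts)
    if (length(v) && any(abs(v - round(v)) > 1e-8))
      msgs <- c(msgs, "raw counts must be integer-valued")
  }
  if ("cellType" %in% colnames(colData(object))) {
    ct <- colData(object)$cellType
    if (anyNA(ct)) msgs <- c(msgs, "cellType labels must not be NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ScBatch from a count matrix
#'
#' @param counts genes x cells matrix (base or Matrix), raw integer counts
#'   unless `normalized = TRUE`. Dimnames are required (genes, cells).
#' @param cellTypes optional character vector of per-cell labels (length
#'   `ncol(counts)`), for reference batches.
#' @param name batch identifier string.
#' @param normalized logical; set by [logNormalize()], rarely by hand.
#' @return an [ScBatch-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' ScBatch(m, cellTypes = c("A", "A", "B", "B"), name = "toy")
#' @export
ScBatch <- function(counts, cellTypes = NULL, name = "batch",
                    normalized = FALSE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopUsage("count matrix must carry gene and cell identifiers as dimnames")
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(cellTypes)) {
    if (length(cellTypes) != ncol(counts))
      .stopUsage("'cellTypes' must have one entry per cell (%d != %d)",
                 length(cellTypes), ncol(counts))
    cd$cellType <- as.character(cellTypes)
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  metadata(sce)$name <- as.character(name)
  metadata(sce)$normalized <- isTRUE(normalized)
  methods::new("ScBatch", sce)
}

#' EmbeddingNetwork: the two-layer metric network f(.; theta)
#'
#' Maps expression profiles in the gene-union space to a low-dimensional
#' embedding: `relu(x W1 + b1) W2 + b2`. Default architecture is a 500-node
#' rectified hidden layer and a 20-dimensional linear output; embeddings are
#' deliberately not length-normalized because the N-pair loss uses raw inner
#' products.
#'
#' @slot W1 input-to-hidden weights, `inputDim x hiddenDim`.
#' @slot b1 hidden bias.
#' @slot W2 hidden-to-output weights, `hiddenDim x embedDim`.
#' @slot b2 output bias.
#' @slot activation hidden nonlinearity (only `"relu"` is provided).
#' @seealso [initNetwork()], [embedCells()], [npairLoss()]
#' @export
setClass("EmbeddingNetwork",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", activation = "character"))

setValidity("EmbeddingNetwork", function(object) {
  msgs <- character()
  if (ncol(object@W1) != length(object@b1))
    msgs <- c(msgs, "b1 length must match ncol(W1)")
  if (nrow(object@W2) != ncol(object@W1))
    msgs <- c(msgs, "W2 rows must match hidden width")
  if (ncol(object@W2) != length(object@b2))
    msgs <- c(msgs, "b2 length must match ncol(W2)")
  if (!all(is.finite(object@W1)) || !all(is.finite(object@W2)) ||
      !all(is.finite(object@b1)) || !all(is.finite(object@b2)))
    msgs <- c(msgs, "parameters must be finite")
  if (!identical(object@activation, "relu"))
    msgs <- c(msgs, "activation must be 'relu'")
  if (length(msgs)) msgs else TRUE
})

#' NPairBatch: one task's sampled anchor/positive tuples
#'
#' N (anchor, positive) cell pairs from N distinct cell types of one
#' reference; the tuple S_i = \{x_i, x_1+, ..., x_N+\} structure of the
#' N-pair loss is implicit in the row pairing.
#'
#' @slot anchors N x G matrix, one anchor expression profile per type.
#' @slot positives N x G matrix, same-type partner of each anchor.
#' @slot cellTypes length-N character, pairwise distinct.
#' @slot anchorIds,positiveIds the sampled cell identifiers.
#' @export
setClass("NPairBatch",
  representation(anchors = "matrix", positives = "matrix",
                 cellTypes = "character", anchorIds = "character",
                 positiveIds = "character"))

setValidity("NPairBatch", function(object) {
  msgs <- character()
  N <- nrow(object@anchors)
  if (N < 2) msgs <- c(msgs, "an N-pair batch needs at least 2 cell types")
  if (nrow(object@positives) != N || length(object@cellTypes) != N)
    msgs <- c(msgs, "anchors, positives and cellTypes must agree in length")
  if (anyDuplicated(object@cellTypes))
    msgs <- c(msgs, "anchor cell types must be pairwise distinct")
  if (any(object@anchorIds == object@positiveIds))
    msgs <- c(msgs, "anchor and positive must be distinct cells")
  if (length(msgs)) msgs else TRUE
})

#' TransformedReference: embedded reference summarized by centroids
#'
#' Per cell type, the arithmetic mean of the embeddings of that type's
#' reference cells; the unit against which query cells are scored.
#'
#' @slot name reference identifier.
#' @slot cellTypes K cell-type labels (no duplicates).
#' @slot centroids K x embedDim matrix, row k = centroid of type k.
#' @seealso [computeCentroids()], [assignCells()]
#' @export
setClass("TransformedReference",
  representation(name = "character", cellTypes = "character",
                 centroids = "matrix"))

setValidity("TransformedReference", function(object) {
  msgs <- character()
  if (length(object@cellTypes) < 1)
    msgs <- c(msgs, "at least one cell type is required")
  if (anyDuplicated(object@cellTypes))
    msgs <- c(msgs, "cell types must be unique")
  if (nrow(object@centroids) != length(object@cellTypes))
    msgs <- c(msgs, "one centroid row per cell type is required")
  if (!all(is.finite(object@centroids)))
    msgs <- c(msgs, "centroids must be finite")
  if (length(msgs)) msgs else TRUE
})

#' MultiRefModel: a trained multi-reference assignment model
#'
#' Bundles the shared embedding network, the frozen gene union (the input
#' feature order), one [TransformedReference-class] per training reference,
#' the resolved training parameters, and the per-epoch loss history.
#'
#' @slot network the shared [EmbeddingNetwork-class].
#' @slot geneUnion character vector; lexicographic union of reference genes.
#' @slot references list of [TransformedReference-class], one per task.
#' @slot config resolved [trainParams()] list.
#' @slot lossHistory numeric, mean per-iteration total loss per epoch.
#' @seealso [trainModel()], [assignCells()], [saveModel()]
#' @export
setClass("MultiRefModel",
  representation(network = "EmbeddingNetwork", geneUnion = "character",
                 references = "list", config = "list",
                 lossHistory = "numeric"))

setValidity("MultiRefModel", function(object) {
  msgs <- character()
  if (length(object@references) < 1)
    msgs <- c(msgs, "at least one trained reference is required")
  ok <- vapply(object@references, methods::is, logical(1),
               class2 = "TransformedReference")
  if (!all(ok)) msgs <- c(msgs, "references must be TransformedReference")
  d <- ncol(object@network@W2)
  bad <- vapply(object@references, function(r) ncol(r@centroids) != d,
                logical(1))
  if (any(bad)) msgs <- c(msgs, "centroid width must equal embedDim")
  nm <- vapply(object@references, function(r) r@name, character(1))
  if (anyDuplicated(nm)) msgs <- c(msgs, "reference names must be unique")
  if (length(msgs)) msgs else TRUE
})
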