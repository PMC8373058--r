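#' Accessors for ScBatch
#'
#' `batchName()` returns the batch identifier; `cellTypes()` the per-cell
#' labels (or `NULL` for a query batch); `isNormalized()` whether
#' [logNormalize()] has been applied; `exprMatrix()` the active expression
#' matrix (the `logcounts` assay once normalized, else raw `counts`).
#'
#' @param x an [ScBatch-class].
#' @return see the description of each accessor.
#' @name ScBatch-accessors
#' @aliases batchName cellTypes isNormalized exprMatrix
NULL

#' @rdname ScBatch-accessors
#' @export
setMethod("batchName", "ScBatch", function(x) metadata(x)$name)

#' @rdname ScBatch-accessors
#' @export
setMethod("cellTypes", "ScBatch", function(x) {
  cd <- colData(x)
  if ("cellType" %in% colnames(cd)) as.character(cd$cellType) else NULL
})

#' @rdname ScBatch-accessors
#' @export
setMethod("isNormalized", "ScBatch", function(x)
  isTRUE(metadata(x)$normalized))

#' @rdname ScBatch-accessors
#' @export
setMethod("exprMatrix", "ScBatch", function(x) {
  if (isNormalized(x) && "logcounts" %in% assayNames(x))
    assay(x, "logcounts")
  else assay(x, "counts")
})

setMethod("show", "ScBatch", function(object) {
  cat(sprintf("ScBatch '%s': %d genes x %d cells (%s)\n",
              batchName(object), nrow(object), ncol(object),
              if (isNormalized(object)) "log-normalized" else "raw counts"))
  ct <- cellTypes(object)
  if (!is.null(ct)) {
    tab <- table(ct)
    cat(sprintf("  %d cell types: %s\n", length(tab),
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  } else cat("  unlabeled (query)\n")
})

setMethod("show", "EmbeddingNetwork", function(object) {
  cat(sprintf("EmbeddingNetwork: %d -> %d (relu) -> %d\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2)))
})

setMethod("show", "TransformedReference", function(object) {
  cat(sprintf("TransformedReference '%s': %d cell-type centroids in %d-d\n",
              object@name, length(object@cellTypes), ncol(object@centroids)))
})

setMethod("show", "MultiRefModel", function(object) {
  cat(sprintf(
    "MultiRefModel: %d reference task(s), %d-gene union, %d-d embedding\n",
    length(object@references), length(object@geneUnion),
    ncol(object@network@W2)))
  for (r in object@references)
    cat(sprintf("  - %s: %d cell types\n", r@name, length(r@cellTypes)))
  lh <- object@lossHistory
  if (length(lh))
    cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                lh[1], lh[length(lh)], length(lh)))
})

#' Names of the trained references in a model
#' @param model a [MultiRefModel-class].
#' @return character vector of reference names.
#' @export
referenceNames <- function(model) {
  vapply(model@references, function(r) r@name, character(1))
}

#' @rdname ScBatch-accessors
#' @export
setMethod("cellTypes", "TransformedReference", function(x) x@cellTypes)

#' @rdname ScBatch-accessors
#' @export
setMethod("cellTypes", "MultiRefModel", function(x)
  .lexSort(unique(unlist(lapply(x@references, function(r) r@cellTypes)))))
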