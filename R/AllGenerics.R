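#' @rdname ScBatch-accessors
#' @export
setGeneric("batchName", function(x) standardGeneric("batchName"))

#' @rdname ScBatch-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname ScBatch-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname ScBatch-accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname qcFilter
#' @export
setGeneric("qcFilter", function(x, thresholds = qcThresholds(), ...)
  standardGeneric("qcFilter"))

#' @rdname filterRareTypes
#' @export
setGeneric("filterRareTypes", function(x, minCells = 10)
  standardGeneric("filterRareTypes"))

#' @rdname logNormalize
#' @export
setGeneric("logNormalize", function(x, scale = 10000)
  standardGeneric("logNormalize"))

#' @rdname alignToUnion
#' @export
setGeneric("alignToUnion", function(x, union)
  standardGeneric("alignToUnion"))

#' @rdname embedCells
#' @export
setGeneric("embedCells", function(net, x) standardGeneric("embedCells"))

#' @rdname npairLoss
#' @export
setGeneric("npairLoss", function(x, batch) standardGeneric("npairLoss"))

#' @rdname computeCentroids
#' @export
setGeneric("computeCentroids", function(net, ref)
  standardGeneric("computeCentroids"))

#' @rdname assignCells
#' @export
setGeneric("assignCells", function(model, query, ...)
  standardGeneric("assignCells"))
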