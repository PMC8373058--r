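#' Initialize an embedding network
#'
#' Two affine maps with a rectified hidden layer and a linear output.
#' Weights are drawn by He initialization (`N(0, 2/fan_in)` for the hidden
#' layer, `N(0, 1/fan_in)` for the linear output), biases start at zero.
#' Reproducible: the same seed yields bitwise-identical parameters.
#'
#' @param inputDim number of input features (the gene-union size).
#' @param hiddenDim hidden-layer width (default 500).
#' @param embedDim embedding dimension (default 20).
#' @param seed integer seed for the weight draws.
#' @return an [EmbeddingNetwork-class].
#' @export
initNetwork <- function(inputDim, hiddenDim = 500, embedDim = 20, seed = 1) {
  inputDim <- .checkCount(inputDim, "inputDim", min = 1)
  hiddenDim <- .checkCount(hiddenDim, "hiddenDim", min = 1)
  embedDim <- .checkCount(embedDim, "embedDim", min = 1)
  set.seed(seed)
  net <- methods::new("EmbeddingNetwork",
    W1 = matrix(stats::rnorm(inputDim * hiddenDim, sd = sqrt(2 / inputDim)),
                inputDim, hiddenDim),
    b1 = numeric(hiddenDim),
    W2 = matrix(stats::rnorm(hiddenDim * embedDim, sd = sqrt(1 / hiddenDim)),
                hiddenDim, embedDim),
    b2 = numeric(embedDim),
    activation = "relu")
  methods::validObject(net)
  net
}

# cells x genes dense matrix for the numeric core
.cellMatrix <- function(x) {
  m <- t(as.matrix(exprMatrix(x)))
  storage.mode(m) <- "double"
  m
}

#' Embed cells into the metric space
#'
#' Applies the network row-wise; each cell's embedding depends only on its
#' own expression vector.
#'
#' @param net an [EmbeddingNetwork-class].
#' @param x a cells x genes numeric matrix in gene-union order, or an
#'   aligned, normalized [ScBatch-class].
#' @return an `nCells x embedDim` matrix (rownames = cell identifiers when
#'   available).
#' @rdname embedCells
#' @export
setMethod("embedCells", signature("EmbeddingNetwork", "matrix"),
  function(net, x) {
    if (ncol(x) != nrow(net@W1))
      .stopUsage("input has %d features but the network expects %d",
                 ncol(x), nrow(net@W1))
    e <- cpp_embed(x, net@W1, net@b1, net@W2, net@b2)
    rownames(e) <- rownames(x)
    e
  })

#' @rdname embedCells
#' @export
setMethod("embedCells", signature("EmbeddingNetwork", "ScBatch"),
  function(net, x) embedCells(net, .cellMatrix(x)))

#' Sample an N-pair batch from a labeled batch
#'
#' Draws, for each cell type, two distinct cells uniformly without
#' replacement as an (anchor, positive) pair, so N equals the batch's
#' cell-type count. Uses R's RNG; seed the stream with `set.seed()` for
#' reproducibility.
#'
#' @param x a labeled, normalized [ScBatch-class] with at least two cell
#'   types, each with at least two cells.
#' @return an [NPairBatch-class].
#' @export
sampleNPairBatch <- function(x) {
  ct <- cellTypes(x)
  if (is.null(ct)) .stopUsage("sampleNPairBatch() requires cell-type labels")
  types <- .lexSort(unique(ct))
  if (length(types) < 2)
    .stopUsage("N-pair batch construction needs >= 2 cell types, '%s' has %d",
               batchName(x), length(types))
  small <- types[vapply(types, function(t) sum(ct == t) < 2, logical(1))]
  if (length(small))
    .stopUsage("cell type(s) with < 2 cells in '%s': %s", batchName(x),
               paste(small, collapse = ", "))
  m <- .cellMatrix(x)
  picks <- vapply(types, function(t) sample(which(ct == t), 2), integer(2))
  a <- picks[1, ]; p <- picks[2, ]
  methods::new("NPairBatch",
    anchors = m[a, , drop = FALSE], positives = m[p, , drop = FALSE],
    cellTypes = types, anchorIds = colnames(x)[a],
    positiveIds = colnames(x)[p])
}

#' N-pair metric-learning loss
#'
#' For N (anchor, positive) pairs from N distinct classes with embeddings
#' `f_i`, `f_i+`, the loss is
#' \deqn{\frac{1}{N}\sum_i \log\Big(1 + \sum_{j \ne i}
#'   \exp(f_i^T f_j^+ - f_i^T f_i^+)\Big),}
#' i.e. an anchor is penalized for being closer (by inner product) to other
#' classes' positives than to its own. Evaluated with a max-shift inside the
#' log-sum so large inner products do not overflow.
#'
#' The `(matrix, matrix)` method takes the anchor and positive embeddings
#' directly (rows aligned by pair); the `(EmbeddingNetwork, NPairBatch)`
#' method embeds the batch first.
#'
#' @param x anchor embeddings (N x d matrix) or an [EmbeddingNetwork-class].
#' @param batch positive embeddings (N x d matrix) or an
#'   [NPairBatch-class].
#' @return a single non-negative number.
#' @examples
#' f <- diag(2)                 # orthonormal, well-separated pairs
#' npairLoss(f, f)              # log(1 + e^-1)
#' @rdname npairLoss
#' @export
setMethod("npairLoss", signature("matrix", "matrix"), function(x, batch) {
  if (!identical(dim(x), dim(batch)))
    .stopUsage("anchor and positive embeddings must have identical shape")
  if (nrow(x) < 2) .stopUsage("the N-pair loss needs N >= 2 pairs")
  L <- x %*% t(batch)                        # L_ij = f_i . f_j+
  D <- L - matrix(diag(L), nrow(L), ncol(L)) # D_ij = L_ij - L_ii
  diag(D) <- -Inf                           # exclude j == i from the sum
  m <- pmax(0, apply(D, 1, max))
  inner <- exp(-m) + rowSums(exp(D - m))
  mean(m + log(inner))
})

#' @rdname npairLoss
#' @export
setMethod("npairLoss", signature("EmbeddingNetwork", "NPairBatch"),
  function(x, batch) {
    npairLoss(embedCells(x, batch@anchors), embedCells(x, batch@positives))
  })

# analytic loss + gradients of one batch, for tests and optimizer checks
.npairGrad <- function(net, anchors, positives) {
  cpp_npair_grad(anchors, positives, net@W1, net@b1, net@W2, net@b2)
}
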