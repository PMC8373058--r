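#' Training parameters
#'
#' Defaults are the standard setting of the method: Adam with initial
#' learning rate 5e-4, 300 epochs, and an L2 regularization rate of 0.05
#' applied as a decoupled weight-decay coefficient. `batchesPerEpoch`
#' defaults to `ceiling(max_t cells_t / (2 N_t))`, so one epoch visits
#' roughly every cell of the largest task once.
#'
#' @param learningRate Adam step size (> 0).
#' @param epochs number of training epochs (>= 1).
#' @param l2Rate decoupled weight-decay coefficient (>= 0).
#' @param batchesPerEpoch iterations per epoch; `NULL` for the default rule.
#' @param seed integer seed controlling initialization and batch sampling.
#' @param hiddenDim hidden-layer width.
#' @param embedDim embedding dimension.
#' @return a classed parameter list for [trainModel()].
#' @export
trainParams <- function(learningRate = 5e-4, epochs = 300, l2Rate = 0.05,
                        batchesPerEpoch = NULL, seed = 1,
                        hiddenDim = 500, embedDim = 20) {
  p <- list(
    learningRate = .checkScalar(learningRate, "learningRate", 0,
                                strict_lower = TRUE),
    epochs = .checkCount(epochs, "epochs", min = 1),
    l2Rate = .checkScalar(l2Rate, "l2Rate", 0),
    batchesPerEpoch = if (is.null(batchesPerEpoch)) NULL else
      .checkCount(batchesPerEpoch, "batchesPerEpoch", min = 1),
    seed = .checkCount(seed, "seed"),
    hiddenDim = .checkCount(hiddenDim, "hiddenDim", min = 1),
    embedDim = .checkCount(embedDim, "embedDim", min = 1))
  class(p) <- "scmrTrainParams"
  p
}

#' Train the parameter-shared metric network on multiple references
#'
#' Each reference is one task. Per iteration, one fresh N-pair batch is
#' sampled from every task (one anchor/positive pair per cell type), the
#' per-task N-pair losses are summed, and a single Adam step with decoupled
#' weight decay updates the fully shared parameters. After training, every
#' reference is embedded and summarized into per-type centroids
#' ([computeCentroids()]). Deterministic given `params$seed`.
#'
#' @param refs list of labeled, normalized [ScBatch-class] references, all
#'   aligned to one gene union (see [preprocessReferences()]).
#' @param params a [trainParams()] list.
#' @param verbose print the loss every 25 epochs.
#' @return a [MultiRefModel-class].
#' @export
trainModel <- function(refs, params = trainParams(), verbose = FALSE) {
  if (methods::is(refs, "ScBatch")) refs <- list(refs)
  if (!length(refs)) .stopUsage("at least one reference task is required")
  union <- rownames(refs[[1]])
  for (r in refs) {
    if (!isNormalized(r))
      .stopUsage("reference '%s' is not normalized", batchName(r))
    if (!identical(rownames(r), union))
      .stopUsage("reference '%s' is not aligned to the common gene union",
                 batchName(r))
  }
  nms <- vapply(refs, batchName, character(1))
  if (anyDuplicated(nms))
    .stopUsage("reference names must be unique: %s",
               paste(nms[duplicated(nms)], collapse = ", "))

  tasks <- lapply(refs, function(r) {
    ct <- cellTypes(r)
    if (is.null(ct))
      .stopUsage("reference '%s' has no cell-type labels", batchName(r))
    types <- .lexSort(unique(ct))
    if (length(types) < 2)
      .stopUsage("reference '%s' is untrainable: %d cell type(s), need >= 2",
                 batchName(r), length(types))
    small <- types[vapply(types, function(t) sum(ct == t) < 2, logical(1))]
    if (length(small))
      .stopUsage("reference '%s' has cell type(s) with < 2 cells: %s",
                 batchName(r), paste(small, collapse = ", "))
    list(x = .cellMatrix(r),
         types = lapply(types, function(t) which(ct == t) - 1L))
  })

  bpe <- params$batchesPerEpoch
  if (is.null(bpe)) {
    perTask <- vapply(seq_along(tasks), function(i)
      ceiling(ncol(refs[[i]]) / (2 * length(tasks[[i]]$types))), numeric(1))
    bpe <- as.integer(max(perTask))
  }

  net <- initNetwork(length(union), params$hiddenDim, params$embedDim,
                     seed = params$seed)
  # initNetwork seeded the RNG; cpp_train's batch sampling continues the stream
  fit <- cpp_train(tasks, net@W1, net@b1, net@W2, net@b2,
                   epochs = params$epochs, batches_per_epoch = bpe,
                   lr = params$learningRate, l2_rate = params$l2Rate)
  net@W1 <- fit$W1; net@b1 <- as.numeric(fit$b1)
  net@W2 <- fit$W2; net@b2 <- as.numeric(fit$b2)
  methods::validObject(net)
  if (verbose) {
    lh <- fit$loss_history
    for (e in unique(c(seq(1, length(lh), by = 25), length(lh))))
      message(sprintf("epoch %3d: summed N-pair loss %.5f", e, lh[e]))
  }

  resolved <- params
  resolved$batchesPerEpoch <- bpe
  model <- methods::new("MultiRefModel",
    network = net, geneUnion = union,
    references = lapply(refs, function(r) computeCentroids(net, r)),
    config = unclass(resolved),
    lossHistory = as.numeric(fit$loss_history))
  methods::validObject(model)
  model
}

.MODEL_FORMAT <- "scMultiRef-model/1"

#' Save / load a trained model
#'
#' The archive is a versioned named list (RDS serialization) holding the
#' network weights, the gene union, the per-reference centroid summaries and
#' the resolved training parameters. `loadModel()` verifies the format tag
#' and fails loudly on truncated or foreign files; a round trip reproduces
#' assignments exactly.
#'
#' @param model a [MultiRefModel-class].
#' @param path file path.
#' @return `saveModel()` the path, invisibly; `loadModel()` the model.
#' @export
saveModel <- function(model, path) {
  if (!methods::is(model, "MultiRefModel"))
    .stopUsage("'model' must be a MultiRefModel")
  obj <- list(
    format = .MODEL_FORMAT,
    network = list(W1 = model@network@W1, b1 = model@network@b1,
                   W2 = model@network@W2, b2 = model@network@b2,
                   activation = model@network@activation),
    geneUnion = model@geneUnion,
    references = lapply(model@references, function(r)
      list(name = r@name, cellTypes = r@cellTypes, centroids = r@centroids)),
    config = model@config,
    lossHistory = model@lossHistory)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) .stopUsage("model file not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    .stopRuntime("cannot load model from %s: %s", path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, .MODEL_FORMAT))
    .stopRuntime("%s is not a %s archive", path, .MODEL_FORMAT)
  net <- methods::new("EmbeddingNetwork",
    W1 = obj$network$W1, b1 = obj$network$b1,
    W2 = obj$network$W2, b2 = obj$network$b2,
    activation = obj$network$activation)
  refs <- lapply(obj$references, function(r)
    methods::new("TransformedReference", name = r$name,
                 cellTypes = r$cellTypes, centroids = r$centroids))
  model <- methods::new("MultiRefModel",
    network = net, geneUnion = obj$geneUnion, references = refs,
    config = obj$config, lossHistory = obj$lossHistory)
  methods::validObject(model)
  model
}
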