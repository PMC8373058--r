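# Experiment drivers: reusable leave-one-batch-out protocols on simulated
# multi-batch data, at desk scale.

# deterministic sub-seeds below 2^31 for nested stochastic steps
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# preprocess references, train, assign the (raw) query, score macro-F1;
# optionally restrict scoring to a subset of true types
.pipelineF1 <- function(refBatches, queryBatch, params,
                        decisionRefs = NULL, restrictTypes = NULL,
                        qc = TRUE, minCells = 10) {
  prep <- preprocessReferences(refBatches, qc = qc, minCells = minCells)
  model <- trainModel(prep$refs, params)
  res <- assignCells(model, queryBatch, decisionRefs = decisionRefs)
  truth <- cellTypes(queryBatch)
  names(truth) <- colnames(queryBatch)
  truth <- truth[res$cell_id]
  pred <- res$predicted_type
  if (!is.null(restrictTypes)) {
    keep <- truth %in% restrictTypes
    truth <- truth[keep]; pred <- pred[keep]
  }
  list(model = model, result = res, macroF1 = macroF1(truth, pred)$macroF1)
}

#' Leave-one-batch-out assignment on simulated data
#'
#' Simulates `cfg`, holds one batch out as the query, trains the multitask
#' model on the remaining batches and scores macro-F1 on the query -- the
#' standard end-to-end check of the method.
#'
#' @param cfg a [simConfig()].
#' @param params a [trainParams()] (its seed drives training).
#' @param queryBatch index of the held-out batch (default 1).
#' @param qc apply default QC to the references.
#' @return list with `macroF1`, the assignment `result`, and the `model`.
#' @export
leaveOneBatchOut <- function(cfg, params = trainParams(epochs = 50),
                             queryBatch = 1, qc = TRUE) {
  batches <- simulateBatches(cfg)
  if (queryBatch < 1 || queryBatch > length(batches))
    .stopUsage("'queryBatch' out of range")
  .pipelineF1(batches[-queryBatch], batches[[queryBatch]], params, qc = qc)
}

#' Reference-count scaling experiment
#'
#' For each repeat, one simulated batch is held out as the query and, for
#' each r in `2:maxRefs`, r of the remaining batches are drawn without
#' replacement as the reference set; the multitask model is trained on them
#' and macro-F1 on the query is recorded. Quantifies how performance scales
#' with the number of available references.
#'
#' @param cfg a [simConfig()] with `nBatches >= maxRefs + 1`.
#' @param maxRefs largest reference count tried.
#' @param repeats number of repeats (fresh simulation + draws per repeat).
#' @param params a [trainParams()].
#' @param seed master seed for the repeat-level randomness.
#' @return data.frame with columns `rep`, `n_refs`, `macro_f1`, `seed`.
#' @export
scalingExperiment <- function(cfg, maxRefs = 5, repeats = 5,
                              params = trainParams(epochs = 50), seed = 1,
                              qc = TRUE) {
  if (cfg$nBatches < maxRefs + 1)
    .stopUsage("scalingExperiment() needs nBatches >= maxRefs + 1 (%d < %d)",
               cfg$nBatches, maxRefs + 1)
  seeds <- .subSeeds(seed, repeats)
  rows <- list()
  for (i in seq_len(repeats)) {
    cfg_i <- cfg; cfg_i$seed <- seeds[i]
    batches <- simulateBatches(cfg_i)
    set.seed(seeds[i])
    qIdx <- sample(length(batches), 1)
    pool <- setdiff(seq_along(batches), qIdx)
    drawSeeds <- sample.int(2147483646L, maxRefs - 1)
    for (r in 2:maxRefs) {
      set.seed(drawSeeds[r - 1])
      sel <- sample(pool, r)
      p <- params; p$seed <- drawSeeds[r - 1]
      fit <- .pipelineF1(batches[sel], batches[[qIdx]], p, qc = qc)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = i, n_refs = r, macro_f1 = fit$macroF1, seed = seeds[i])
    }
  }
  do.call(rbind, rows)
}

#' Multitask benefit on confusable cell types
#'
#' On a design whose confusable type pair is hard to separate within any
#' single batch but carries a consistent weak signal across batches, trains
#' (a) the multitask model on all training batches and (b) a single-task
#' model on each training batch alone, and scores macro-F1 on the held-out
#' query restricted to the confusable types.
#'
#' @param cfg a [simConfig()] with `confusablePairs` set.
#' @param params a [trainParams()].
#' @param seed seed for simulation and training.
#' @param queryBatch index of the held-out batch.
#' @return list with `multitask` (score), `single` (named vector, one score
#'   per single-reference model) and `confusableTypes`.
#' @export
multitaskBenefitExperiment <- function(cfg,
                                       params = trainParams(epochs = 50),
                                       seed = 1, queryBatch = 1, qc = TRUE) {
  if (is.null(cfg$confusablePairs))
    .stopUsage("'cfg' must define confusablePairs")
  confTypes <- unique(unlist(cfg$confusablePairs))
  cfg$seed <- seed
  batches <- simulateBatches(cfg)
  query <- batches[[queryBatch]]
  trainSet <- batches[-queryBatch]
  p <- params; p$seed <- seed
  multi <- .pipelineF1(trainSet, query, p, restrictTypes = confTypes,
                       qc = qc)$macroF1
  single <- vapply(trainSet, function(b)
    .pipelineF1(list(b), query, p, restrictTypes = confTypes, qc = qc)$macroF1,
    numeric(1))
  names(single) <- vapply(trainSet, batchName, character(1))
  list(multitask = multi, single = single, confusableTypes = confTypes)
}

#' Cross-species style protocol
#'
#' One batch plays the target species: after QC, a stratified
#' `targetFraction` split of its cells becomes the only in-decision
#' reference and the remainder the query. The other batches -- simulated
#' with inflated batch distortion to stand in for related datasets from
#' another species -- participate in training only. Compares the multitask
#' model (target reference + auxiliary batches, decision set = target
#' reference alone) with a single-task model trained on the small target
#' reference by itself.
#'
#' @param cfg a [simConfig()]; its `batchSeverity` applies to the target
#'   batch, auxiliary batches get `auxSeverityFactor` times it.
#' @param targetFraction fraction of the target batch used as reference
#'   (0 < f < 1).
#' @param params a [trainParams()].
#' @param seed seed for simulation, split and training.
#' @param auxSeverityFactor batch-severity inflation of the auxiliary
#'   ("other species") batches.
#' @return list with `multitask`, `single` (macro-F1 on the query) and
#'   `decisionReferences` (names actually consulted at decision time).
#' @export
crossSpeciesExperiment <- function(cfg, targetFraction = 0.1,
                                   params = trainParams(epochs = 50),
                                   seed = 1, auxSeverityFactor = 2,
                                   qc = TRUE) {
  targetFraction <- .checkScalar(targetFraction, "targetFraction", 0, 1)
  if (targetFraction <= 0 || targetFraction >= 1)
    .stopUsage("'targetFraction' must be strictly between 0 and 1")
  sev <- cfg$batchSeverity[1]
  cfg$batchSeverity <- c(sev, rep(sev * auxSeverityFactor, cfg$nBatches - 1))
  cfg$seed <- seed
  batches <- simulateBatches(cfg)
  target <- if (qc) qcFilter(batches[[1]]) else batches[[1]]
  aux <- batches[-1]

  # stratified split of the QC'd target batch
  set.seed(seed)
  ct <- cellTypes(target)
  refIdx <- unlist(lapply(unique(ct), function(t) {
    idx <- which(ct == t)
    sample(idx, ceiling(targetFraction * length(idx)))
  }))
  refPart <- target[, sort(refIdx)]
  metadata(refPart)$name <- "target_ref"
  queryPart <- target[, setdiff(seq_len(ncol(target)), refIdx)]
  metadata(queryPart)$name <- "target_query"

  p <- params; p$seed <- seed
  multi <- .pipelineF1(c(list(refPart), aux), queryPart, p,
                       decisionRefs = "target_ref", qc = qc)
  single <- .pipelineF1(list(refPart), queryPart, p, qc = qc)
  list(multitask = multi$macroF1, single = single$macroF1,
       decisionReferences = unique(multi$result$source_reference))
}
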