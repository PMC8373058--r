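#' Simulation configuration for multi-batch count data
#'
#' Describes a synthetic multi-batch scRNA-seq design with controlled
#' cell-type signal and batch-specific distortion:
#' \itemize{
#'   \item per-gene baseline means are log-normal (`meanlog`, sdlog 1), with
#'     a small block of mitochondrial genes (`MT-` prefix) at an elevated
#'     baseline so QC mito fractions are realistic;
#'   \item each cell type up-regulates `markerGenesPerType` marker genes by
#'     `exp(markerLogFold)`;
#'   \item each batch multiplies every gene mean by its own fixed log-normal
#'     factor with log-sd `batchSeverity` (0 = all batches share one
#'     distribution);
#'   \item counts are negative binomial (gamma-Poisson) with the given
#'     dispersion, and cells carry a log-normal library-size factor.
#' }
#' `confusablePairs` names pairs of types that share
#' `confusableSharedFrac` of their markers at full fold while their
#' remaining, type-distinct markers are attenuated to
#' `markerLogFold * confusableFoldFactor` -- confusable within any single
#' batch, but with a consistent weak signal across batches.
#'
#' @param nGenes total genes, including `nMitoGenes` mitochondrial ones.
#' @param cellTypes named vector: cells per type per batch.
#' @param nBatches number of batches.
#' @param markerGenesPerType markers per type.
#' @param markerLogFold marker effect on the natural-log scale.
#' @param batchSeverity per-gene batch log-sd; scalar or one value per batch.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param confusablePairs list of length-2 character vectors of type names.
#' @param confusableSharedFrac fraction of a confusable type's markers
#'   shared with its partner.
#' @param confusableFoldFactor attenuation of the distinct markers.
#' @param libSizeSdLog log-sd of the per-cell library-size factor.
#' @param nMitoGenes,mitoBoost mitochondrial block size and baseline boost.
#' @param meanlog baseline log-mean (calibrated so default cells pass the
#'   default [qcThresholds()]).
#' @param seed integer seed; the same config is bitwise-reproducible.
#' @return a classed configuration list for [simulateBatches()].
#' @export
simConfig <- function(nGenes = 1000,
                      cellTypes = c(A = 60, B = 60, C = 60, D = 60),
                      nBatches = 4, markerGenesPerType = 10,
                      markerLogFold = 2, batchSeverity = 0.5,
                      dispersion = 0.3, confusablePairs = NULL,
                      confusableSharedFrac = 0.8,
                      confusableFoldFactor = 0.3, libSizeSdLog = 0.2,
                      nMitoGenes = 10, mitoBoost = 4, meanlog = 1.0,
                      seed = 1) {
  if (is.null(names(cellTypes)) || anyDuplicated(names(cellTypes)))
    .stopUsage("'cellTypes' must be a named vector with unique type names")
  nBatches <- .checkCount(nBatches, "nBatches", min = 1)
  sev <- as.numeric(batchSeverity)
  if (length(sev) == 1) sev <- rep(sev, nBatches)
  if (length(sev) != nBatches || any(sev < 0))
    .stopUsage("'batchSeverity' must be a non-negative scalar or one value per batch")
  if (!is.null(confusablePairs)) {
    for (p in confusablePairs)
      if (length(p) != 2 || !all(p %in% names(cellTypes)))
        .stopUsage("each confusable pair must name two configured cell types")
  }
  cfg <- list(
    nGenes = .checkCount(nGenes, "nGenes", min = 1),
    cellTypes = cellTypes,
    nBatches = nBatches,
    markerGenesPerType = .checkCount(markerGenesPerType,
                                     "markerGenesPerType", min = 1),
    markerLogFold = .checkScalar(markerLogFold, "markerLogFold", 0),
    batchSeverity = sev,
    dispersion = .checkScalar(dispersion, "dispersion", 0,
                              strict_lower = TRUE),
    confusablePairs = confusablePairs,
    confusableSharedFrac = .checkScalar(confusableSharedFrac,
                                        "confusableSharedFrac", 0, 1),
    confusableFoldFactor = .checkScalar(confusableFoldFactor,
                                        "confusableFoldFactor", 0, 1),
    libSizeSdLog = .checkScalar(libSizeSdLog, "libSizeSdLog", 0),
    nMitoGenes = .checkCount(nMitoGenes, "nMitoGenes"),
    mitoBoost = .checkScalar(mitoBoost, "mitoBoost", 1),
    meanlog = .checkScalar(meanlog, "meanlog"),
    seed = .checkCount(seed, "seed"))
  if (cfg$nMitoGenes >= cfg$nGenes)
    .stopUsage("'nMitoGenes' must be smaller than 'nGenes'")
  need <- length(cellTypes) * cfg$markerGenesPerType
  if (need > cfg$nGenes - cfg$nMitoGenes)
    .stopUsage("not enough non-mitochondrial genes for the marker sets")
  class(cfg) <- "scmrSimConfig"
  cfg
}

# per-type fold-change matrix (types x genes) encoding markers and
# confusable-pair structure
.typeFolds <- function(cfg, pool) {
  types <- names(cfg$cellTypes)
  folds <- matrix(1, length(types), cfg$nGenes,
                  dimnames = list(types, NULL))
  full <- exp(cfg$markerLogFold)
  weak <- exp(cfg$markerLogFold * cfg$confusableFoldFactor)
  mpt <- cfg$markerGenesPerType
  take <- local({
    i <- 0
    function(k) { out <- pool[(i + 1):(i + k)]; i <<- i + k; out }
  })
  inPair <- character()
  for (p in cfg$confusablePairs %||% list()) {
    nShared <- round(cfg$confusableSharedFrac * mpt)
    shared <- take(nShared)
    for (t in p) {
      own <- take(mpt - nShared)
      folds[t, shared] <- full
      folds[t, own] <- weak
    }
    inPair <- c(inPair, p)
  }
  for (t in setdiff(types, inPair))
    folds[t, take(mpt)] <- full
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate multi-batch labeled count data
#'
#' Draws the shared biology (baselines, marker assignments) once from the
#' seed, then per batch a fixed per-gene distortion factor and per cell
#' negative-binomial counts. Batches share cell types and marker structure;
#' only the batch factors (and sampling noise) differ, emulating several
#' experiments measuring the same tissue.
#'
#' Each returned batch stores its expected per-type gene-mean matrix
#' (before library-size scaling) in `metadata(.)$typeMeans`.
#'
#' @param cfg a [simConfig()] list.
#' @return named list of labeled [ScBatch-class] objects
#'   (`batch1 ... batchN`).
#' @export
simulateBatches <- function(cfg) {
  stopifnot(inherits(cfg, "scmrSimConfig"))
  set.seed(cfg$seed)
  G <- cfg$nGenes
  nMito <- cfg$nMitoGenes
  geneIds <- c(if (nMito) paste0("MT-", seq_len(nMito)),
               sprintf("G%04d", seq_len(G - nMito)))
  baseline <- stats::rlnorm(G, meanlog = cfg$meanlog, sdlog = 1)
  if (nMito) baseline[seq_len(nMito)] <- baseline[seq_len(nMito)] * cfg$mitoBoost
  pool <- sample(setdiff(seq_len(G), seq_len(nMito)))
  folds <- .typeFolds(cfg, pool)
  types <- names(cfg$cellTypes)
  size <- 1 / cfg$dispersion

  batches <- vector("list", cfg$nBatches)
  for (b in seq_len(cfg$nBatches)) {
    sev <- cfg$batchSeverity[b]
    gamma <- if (sev > 0) stats::rlnorm(G, 0, sev) else rep(1, G)
    typeMeans <- matrix(NA_real_, G, length(types),
                        dimnames = list(geneIds, types))
    counts <- NULL
    labels <- character()
    for (t in types) {
      n <- cfg$cellTypes[[t]]
      mu0 <- baseline * folds[t, ] * gamma
      typeMeans[, t] <- mu0
      s <- stats::rlnorm(n, 0, cfg$libSizeSdLog)
      mu <- outer(mu0, s)
      cts <- matrix(stats::rnbinom(G * n, mu = mu, size = size), G, n)
      counts <- cbind(counts, cts)
      labels <- c(labels, rep(t, n))
    }
    name <- paste0("batch", b)
    dimnames(counts) <- list(geneIds,
                             sprintf("%s_c%04d", name, seq_len(ncol(counts))))
    sb <- ScBatch(Matrix::Matrix(counts, sparse = TRUE),
                  cellTypes = labels, name = name)
    metadata(sb)$typeMeans <- typeMeans
    batches[[b]] <- sb
  }
  names(batches) <- paste0("batch", seq_len(cfg$nBatches))
  batches
}

#' Write simulated batches to a directory
#'
#' One matrix + label-table pair per batch, in a format readable by
#' [readExpressionMatrix()].
#'
#' @param batches list of [ScBatch-class] (e.g. from [simulateBatches()]).
#' @param dir output directory.
#' @param format `"delimited"` or `"matrix_market"`.
#' @return invisibly, the directory.
#' @export
writeBatches <- function(batches, dir,
                         format = c("delimited", "matrix_market")) {
  format <- match.arg(format)
  for (b in batches) writeBatch(b, dir, format)
  invisible(dir)
}

#' Preset simulation designs
#'
#' Canonical configurations for the package's study designs:
#' \describe{
#'   \item{separable}{4 batches x 4 types x 60 cells, marker log-fold 2,
#'     batch severity 0.5: well-separated types for end-to-end recovery
#'     checks.}
#'   \item{confusable}{as `separable` but types A and B share half of their
#'     16 markers at full strength while their own markers are attenuated to
#'     30% of the log-fold, and batch severity is 0.6. Within one batch the
#'     pair is near the edge of separability; the weak distinct signal is
#'     spread over several genes so it is recoverable jointly across
#'     batches -- the regime where multitask training pays off.}
#'   \item{scaling}{as `separable` with 6 batches, for reference-count
#'     scaling runs.}
#'   \item{crossSpecies}{as `confusable` with 150 cells per type per batch,
#'     sized so a 10% stratified split of one batch still clears the
#'     rare-type filter.}
#' }
#'
#' @param design one of `"separable"`, `"confusable"`, `"scaling"`,
#'   `"crossSpecies"`.
#' @param ... overrides passed on to [simConfig()].
#' @return a [simConfig()] list.
#' @export
presetConfig <- function(design = c("separable", "confusable", "scaling",
                                    "crossSpecies"), ...) {
  design <- match.arg(design)
  args <- switch(design,
    separable = list(),
    confusable = list(markerGenesPerType = 16, batchSeverity = 0.6,
                      confusablePairs = list(c("A", "B")),
                      confusableSharedFrac = 0.5,
                      confusableFoldFactor = 0.3),
    scaling = list(nBatches = 6),
    crossSpecies = list(cellTypes = c(A = 150, B = 150, C = 150, D = 150),
                        markerGenesPerType = 16, batchSeverity = 0.6,
                        confusablePairs = list(c("A", "B")),
                        confusableSharedFrac = 0.5,
                        confusableFoldFactor = 0.3))
  do.call(simConfig, utils::modifyList(args, list(...)))
}
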