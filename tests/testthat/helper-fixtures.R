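# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

suppressPackageStartupMessages(library(Matrix))

# genes x cells ScBatch from a dense matrix, with auto dimnames
makeBatch <- function(m, types = NULL, name = "toy", genes = NULL,
                      cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  ScBatch(Matrix::Matrix(m, sparse = TRUE), cellTypes = types, name = name)
}

# small multi-batch simulation usable without cell QC (tiny gene panel)
smallSimCfg <- function(...) {
  args <- list(...)
  defaults <- list(nGenes = 120, cellTypes = c(A = 20, B = 20, C = 20),
                   nBatches = 3, markerGenesPerType = 6, markerLogFold = 2,
                   batchSeverity = 0.4, nMitoGenes = 4, libSizeSdLog = 0.1,
                   seed = 1)
  do.call(simConfig, utils::modifyList(defaults, args))
}

tinyTrainParams <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 10, hiddenDim = 48, embedDim = 8, seed = 1)
  do.call(trainParams, utils::modifyList(defaults, args))
}

# Constructed QC/rare-type plumbing toy with fully known outcomes under the
# default thresholds (>500 genes, >1500 UMIs, <10% mito, <10 cells rare).
#
# 24 cells, 1000 genes (10 mitochondrial):
#   fail_genes  : 400 detected genes, total 2000, no mito      -> QC fail (genes)
#   fail_umi    : 600 detected, total exactly 1500             -> QC fail (umi)
#   fail_mito_eq: 610 detected, total 2000, mito exactly 10%   -> QC fail (strict)
#   fail_mito_hi: 610 detected, total 2250, mito 20%           -> QC fail (mito)
#   fail_all    : 110 detected, total 300, mito 33%            -> QC fail (all)
#   X01..X09    : pass QC, type X (9 cells)                    -> rare, dropped
#   Y01..Y10    : pass QC, type Y (10 cells)                   -> retained
qcPlumbingToy <- function() {
  nGenes <- 1000
  genes <- c(paste0("MT-", 1:10), sprintf("G%03d", 1:990))
  cells <- c("fail_genes", "fail_umi", "fail_mito_eq", "fail_mito_hi",
             "fail_all", sprintf("X%02d", 1:9), sprintf("Y%02d", 1:10))
  m <- matrix(0L, nGenes, length(cells), dimnames = list(genes, cells))
  nonMito <- 11:1000
  m[nonMito[1:400], "fail_genes"] <- 5L      # 400 detected, 2000 total
  m[nonMito[1:599], "fail_umi"] <- 2L        # 600 detected
  m[nonMito[600], "fail_umi"] <- 302L        # total exactly 1500
  m[nonMito[1:600], "fail_mito_eq"] <- 3L    # 1800 non-mito
  m[1:10, "fail_mito_eq"] <- 20L             # 200 mito -> 200/2000 = 10%
  m[nonMito[1:600], "fail_mito_hi"] <- 3L    # 1800 non-mito
  m[1:10, "fail_mito_hi"] <- 45L             # 450 mito -> 450/2250 = 20%
  m[nonMito[1:100], "fail_all"] <- 2L        # 110 detected, 200 non-mito
  m[1:10, "fail_all"] <- 10L                 # 100 mito -> 100/300 = 33%
  passers <- c(sprintf("X%02d", 1:9), sprintf("Y%02d", 1:10))
  for (cc in passers) {
    m[nonMito[1:600], cc] <- 3L              # 610 detected, 1800 non-mito
    m[1:10, cc] <- 2L                        # 20 mito -> 20/1820 ~ 1.1%
  }
  types <- c(rep("X", 5), rep("X", 9), rep("Y", 10))
  makeBatch(m, types = types, name = "qc_toy", genes = genes, cells = cells)
}

.lexSortForTest <- function(x) sort(x, method = "radix")

# independent brute-force N-pair loss: scalar double loop over the printed
# formula, no shared code with the package implementation
bruteNpairLoss <- function(F, Fp) {
  N <- nrow(F)
  total <- 0
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      s <- s + exp(sum(F[i, ] * Fp[j, ]) - sum(F[i, ] * Fp[i, ]))
    }
    total <- total + log(1 + s)
  }
  total / N
}

# independent macro-F1 oracle via an explicit confusion matrix
confusionMacroF1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  labs <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = labs), factor(pred, levels = labs))
  f1s <- vapply(classes, function(cl) {
    tp <- cm[cl, cl]
    p <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    r <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(f1s)
}

# preprocess tiny references without QC (gene panels far below the default
# detected-genes threshold) and train briefly
fitSmallModel <- function(batches, params = tinyTrainParams()) {
  prep <- preprocessReferences(batches, qc = FALSE)
  trainModel(prep$refs, params)
}
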