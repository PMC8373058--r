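#' Summarize a reference by cell-type centroids in embedding space
#'
#' Embeds every reference cell and averages the embeddings per cell type
#' (plain arithmetic mean of the unnormalized embeddings).
#'
#' @param net the trained [EmbeddingNetwork-class].
#' @param ref a labeled, normalized, union-aligned [ScBatch-class].
#' @return a [TransformedReference-class].
#' @rdname computeCentroids
#' @export
setMethod("computeCentroids", signature("EmbeddingNetwork", "ScBatch"),
  function(net, ref) {
    ct <- cellTypes(ref)
    if (is.null(ct)) .stopUsage("computeCentroids() requires cell-type labels")
    emb <- embedCells(net, ref)
    types <- .lexSort(unique(ct))
    cent <- rowsum(emb, group = factor(ct, levels = types)) /
      as.vector(table(factor(ct, levels = types)))
    stopifnot(all(is.finite(cent)))
    methods::new("TransformedReference", name = batchName(ref),
                 cellTypes = types,
                 centroids = unname(cent))
  })

#' Pearson similarity between embedding vectors
#'
#' Standard Pearson correlation coefficient. A constant (zero-variance)
#' vector has no defined correlation; such inputs yield `-Inf` with a
#' warning, so degenerate centroids or embeddings can never win an
#' assignment.
#'
#' @param u,v numeric vectors of equal length (>= 2).
#' @return a number in `[-1, 1]`, or `-Inf` for degenerate input.
#' @examples
#' pearsonSimilarity(c(1, 2, 3), c(3, 2, 1))   # -1
#' @export
pearsonSimilarity <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2)
    .stopUsage("'u' and 'v' must be equal-length vectors of length >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("constant vector in Pearson similarity; returning -Inf",
            call. = FALSE)
    return(-Inf)
  }
  stats::cor(u, v)
}

# centroid table of the decision set, columns ordered by (reference, type)
# so ties in similarity resolve deterministically by that lexicographic order
.decisionCentroids <- function(model, decisionRefs) {
  nms <- referenceNames(model)
  if (is.null(decisionRefs)) decisionRefs <- nms
  unknown <- setdiff(decisionRefs, nms)
  if (length(unknown))
    .stopUsage("unknown decision reference(s): %s",
               paste(unknown, collapse = ", "))
  if (!length(decisionRefs)) .stopUsage("the decision set must not be empty")
  refs <- model@references[match(decisionRefs, nms)]
  tab <- do.call(rbind, lapply(refs, function(r)
    data.frame(reference = r@name, cell_type = r@cellTypes,
               stringsAsFactors = FALSE)))
  cent <- do.call(rbind, lapply(refs, function(r) r@centroids))
  ord <- order(tab$reference, tab$cell_type, method = "radix")
  list(table = tab[ord, , drop = FALSE], centroids = cent[ord, , drop = FALSE])
}

#' Assign query cells by decision-level integration
#'
#' Each query cell is embedded once; its Pearson similarity to every
#' cell-type centroid of every reference in the decision set is computed,
#' and the cell receives the label (and source reference) of the maximal
#' similarity. Every cell is assigned -- there is no "unassigned" outcome.
#' Ties are broken by (reference name, cell type) lexicographic order.
#'
#' A raw-count query is normalized and aligned to the model's gene union
#' automatically; set `qc = TRUE` to also apply cell QC to the query.
#'
#' @param model a [MultiRefModel-class].
#' @param query an [ScBatch-class].
#' @param decisionRefs optional character vector restricting the decision
#'   set to a subset of trained reference names (e.g. the within-species
#'   reference in a cross-species protocol; the other references still
#'   shaped the embedding during training).
#' @param qc apply [qcFilter()] to a raw query (default FALSE).
#' @param thresholds thresholds when `qc = TRUE`.
#' @param returnSimilarities also return the full long-format similarity
#'   table as attribute `"similarities"`.
#' @param ... unused.
#' @return a data.frame with columns `cell_id`, `predicted_type`,
#'   `best_similarity`, `source_reference`.
#' @rdname assignCells
#' @export
setMethod("assignCells", signature("MultiRefModel", "ScBatch"),
  function(model, query, decisionRefs = NULL, qc = FALSE,
           thresholds = qcThresholds(), returnSimilarities = FALSE, ...) {
    dec <- .decisionCentroids(model, decisionRefs)
    if (!isNormalized(query) || !identical(rownames(query), model@geneUnion))
      query <- prepareQuery(query, model@geneUnion, qc = qc,
                            thresholds = thresholds)
    emb <- embedCells(model@network, query)
    # columns of cor() output = centroids; rows = query cells
    sims <- suppressWarnings(stats::cor(t(emb), t(dec$centroids)))
    if (anyNA(sims)) {
      warning("degenerate constant embedding(s) encountered; ",
              "their similarities were set to -Inf", call. = FALSE)
      sims[is.na(sims)] <- -Inf
    }
    best <- max.col(sims, ties.method = "first")
    res <- data.frame(
      cell_id = colnames(query),
      predicted_type = dec$table$cell_type[best],
      best_similarity = sims[cbind(seq_len(nrow(sims)), best)],
      source_reference = dec$table$reference[best],
      stringsAsFactors = FALSE)
    if (returnSimilarities) {
      long <- data.frame(
        cell_id = rep(colnames(query), times = nrow(dec$table)),
        reference = rep(dec$table$reference, each = nrow(sims)),
        cell_type = rep(dec$table$cell_type, each = nrow(sims)),
        similarity = as.vector(sims),
        stringsAsFactors = FALSE)
      attr(res, "similarities") <- long
    }
    res
  })

#' Write assignment results to TSV
#'
#' @param res result of [assignCells()].
#' @param path output TSV path.
#' @param similarityPath optional path for the long-format similarity table
#'   (requires `returnSimilarities = TRUE` in [assignCells()]).
#' @return invisibly, `path`.
#' @export
writeAssignments <- function(res, path, similarityPath = NULL) {
  data.table::fwrite(res, path, sep = "\t")
  if (!is.null(similarityPath)) {
    sims <- attr(res, "similarities")
    if (is.null(sims))
      .stopUsage("no similarity table attached; call assignCells(..., returnSimilarities = TRUE)")
    data.table::fwrite(sims, similarityPath, sep = "\t")
  }
  invisible(path)
}
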