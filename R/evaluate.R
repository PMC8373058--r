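#' Macro-F1 score and per-class metrics
#'
#' For each of the N distinct cell types in `truth`, precision and recall
#' are computed from the confusion counts and combined as
#' F1 = 2PR/(P+R); the macro-F1 is the unweighted mean of the N per-class
#' F1 values. Classes are enumerated from the truth labels only: a label
#' that is predicted but never true contributes false positives to other
#' classes but adds no class of its own. A 0/0 precision, recall or F1 is
#' defined as 0, so a truth class that is never predicted still counts in
#' the average.
#'
#' @param truth character vector of true cell types (non-empty).
#' @param predicted character vector of predicted types, same length.
#' @return list with `macroF1` (number in `[0, 1]`) and `classMetrics`
#'   (data.frame: cell_type, precision, recall, f1, support).
#' @examples
#' macroF1(c("A", "A", "B"), c("A", "B", "B"))$macroF1   # 2/3
#' @export
macroF1 <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!length(truth)) .stopUsage("'truth' must be non-empty")
  if (length(truth) != length(predicted))
    .stopUsage("'truth' and 'predicted' differ in length (%d vs %d)",
               length(truth), length(predicted))
  classes <- .lexSort(unique(truth))
  metrics <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(cell_type = cl, precision = precision, recall = recall,
               f1 = f1, support = tp + fn, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, metrics)
  list(macroF1 = mean(metrics$f1), classMetrics = metrics)
}
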