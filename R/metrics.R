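## Inter-rater evaluation: confusion table, per-stage recall/precision/f1,
## agreement rate (accuracy) and Cohen's kappa, in the fixed stage order
## Wake, NREM, REM.

.asStageVector <- function(x) {
  if (is(x, "Hypnogram")) x@stages else as.integer(x)
}

#' Confusion table between two stage sequences
#'
#' Rows are the reference rater's stages, columns the predicted stages, in
#' the fixed order Wake, NREM, REM.
#'
#' @param reference,predicted [Hypnogram-class] objects or integer vectors
#'   of stage codes, equal length, non-empty.
#' @return 3x3 integer matrix with dimnames `reference` x `predicted`.
#' @export
confusionTable <- function(reference, predicted) {
  r <- .asStageVector(reference); p <- .asStageVector(predicted)
  .stopifnot1(length(r) == length(p),
              "reference and predicted lengths differ (", length(r), " vs ",
              length(p), ")")
  .stopifnot1(length(r) > 0, "empty stage sequences")
  .stopifnot1(all(r %in% 1:3) && all(p %in% 1:3), "invalid stage codes")
  tab <- matrix(0L, 3L, 3L,
                dimnames = list(reference = STAGE_NAMES,
                                predicted = STAGE_NAMES))
  cnt <- table(factor(r, 1:3), factor(p, 1:3))
  tab[] <- as.integer(cnt)
  tab
}

#' Per-stage recall, precision and f1
#'
#' `recall_s = TP / (TP + FN)`, `precision_s = TP / (TP + FP)`,
#' `f1_s = 2 / (recall_s^-1 + precision_s^-1)`. A stage absent from a rater
#' (0/0) yields `NaN` for the undefined quantity and for its f1.
#'
#' @param tab 3x3 confusion table from [confusionTable()].
#' @return data.frame with columns `stage`, `recall`, `precision`, `f1`.
#' @export
stageMetrics <- function(tab) {
  tp <- diag(tab)
  recall <- tp / rowSums(tab)
  precision <- tp / colSums(tab)
  f1 <- 2 / (1 / recall + 1 / precision)
  f1[is.nan(recall) | is.nan(precision)] <- NaN
  data.frame(stage = STAGE_NAMES, recall = as.numeric(recall),
             precision = as.numeric(precision), f1 = as.numeric(f1),
             stringsAsFactors = FALSE)
}

#' Agreement rate (accuracy) of a confusion table
#'
#' Fraction of epochs on which the two raters agree: `trace / total`.
#'
#' @param tab 3x3 confusion table.
#' @return numeric(1) in `[0, 1]`.
#' @export
agreementRate <- function(tab) {
  sum(diag(tab)) / sum(tab)
}

#' Cohen's kappa of a confusion table
#'
#' `kappa = (accuracy - p_e) / (1 - p_e)` with chance agreement
#' `p_e = sum_s row_s * col_s / total^2`. In the degenerate case `p_e = 1`
#' (both raters constant with identical marginals), kappa is defined as 1
#' when accuracy is 1 and 0 otherwise.
#'
#' @param tab 3x3 confusion table with positive total.
#' @return numeric(1) in `[-1, 1]`.
#' @export
cohensKappa <- function(tab) {
  n <- sum(tab)
  .stopifnot1(n > 0, "empty confusion table")
  acc <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - 1e-15) return(if (acc >= 1 - 1e-15) 1 else 0)
  (acc - pe) / (1 - pe)
}

#' Full evaluation report for one pair of stage sequences
#'
#' @inheritParams confusionTable
#' @return list with `confusion` (3x3 table), `per_stage` (data.frame from
#'   [stageMetrics()]), `accuracy`, `kappa` and `n_epochs`.
#' @export
metricsReport <- function(reference, predicted) {
  tab <- confusionTable(reference, predicted)
  list(confusion = tab, per_stage = stageMetrics(tab),
       accuracy = agreementRate(tab), kappa = cohensKappa(tab),
       n_epochs = sum(tab))
}

#' Per-recording evaluation with threshold summary
#'
#' Evaluates each recording's prediction against its reference and appends a
#' pooled row over all epochs. The fraction of recordings whose accuracy and
#' per-stage f1 exceed 0.9, and whose kappa and f1 exceed 0.8, is attached
#' as the `"threshold_summary"` attribute. Note that pooled kappa is not the
#' mean of per-recording kappas (the marginals differ across recordings).
#'
#' @param references,predictions lists of [Hypnogram-class] objects (or
#'   integer vectors), parallel, one element per recording.
#' @param recordingIds recording identifiers (default `rec1`, `rec2`, ...).
#' @return data.frame with one row per recording plus a `"pooled"` row:
#'   `recording_id`, `n_epochs`, `accuracy`, `kappa`, and
#'   `recall`/`precision`/`f1` per stage.
#' @export
perRecordingReport <- function(references, predictions,
                               recordingIds = NULL) {
  .stopifnot1(length(references) == length(predictions),
              "reference and prediction lists differ in length")
  if (is.null(recordingIds))
    recordingIds <- paste0("rec", seq_along(references))
  row1 <- function(id, ref, pred) {
    m <- metricsReport(ref, pred)
    ps <- m$per_stage
    out <- data.frame(recording_id = id, n_epochs = m$n_epochs,
                      accuracy = m$accuracy, kappa = m$kappa,
                      stringsAsFactors = FALSE)
    for (s in seq_len(3)) {
      out[[paste0("recall_", ps$stage[s])]] <- ps$recall[s]
      out[[paste0("precision_", ps$stage[s])]] <- ps$precision[s]
      out[[paste0("f1_", ps$stage[s])]] <- ps$f1[s]
    }
    out
  }
  rows <- do.call(rbind, Map(row1, recordingIds, references, predictions))
  pooledRef <- unlist(lapply(references, .asStageVector))
  pooledPred <- unlist(lapply(predictions, .asStageVector))
  rows <- rbind(rows, row1("pooled", pooledRef, pooledPred))
  rownames(rows) <- NULL
  per <- rows[rows$recording_id != "pooled", , drop = FALSE]
  f1cols <- paste0("f1_", STAGE_NAMES)
  attr(rows, "threshold_summary") <- c(
    frac_accuracy_gt_0.9 = mean(per$accuracy > 0.9),
    frac_kappa_gt_0.8 = mean(per$kappa > 0.8),
    stats::setNames(colMeans(per[f1cols] > 0.9, na.rm = TRUE),
                    paste0("frac_", f1cols, "_gt_0.9")),
    stats::setNames(colMeans(per[f1cols] > 0.8, na.rm = TRUE),
                    paste0("frac_", f1cols, "_gt_0.8")))
  rows
}

#' Print a confusion table with recall and precision annotations
#'
#' Renders row-percentage (recall on the diagonal) values with the
#' column-percentage (precision on the diagonal) in parentheses, the dual
#' annotation style commonly used for sleep-scoring confusion heatmaps.
#'
#' @param tab 3x3 confusion table.
#' @return character matrix of formatted cells, invisibly; printed as a side
#'   effect.
#' @export
formatConfusion <- function(tab) {
  rowPct <- sweep(tab, 1L, pmax(rowSums(tab), 1L), "/") * 100
  colPct <- sweep(tab, 2L, pmax(colSums(tab), 1L), "/") * 100
  cells <- matrix(sprintf("%5.1f%% (%5.1f%%)", rowPct, colPct), 3L, 3L,
                  dimnames = dimnames(tab))
  print(cells, quote = FALSE)
  invisible(cells)
}
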