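#' Per-epoch additive (SHAP) feature attributions
#'
#' Exact tree-path-dependent SHAP values of the gradient-boosted model: for
#' every epoch and stage class, an additive decomposition of the class
#' margin over the features. The local-accuracy identity
#' `baseValue + sum(contributions) = margin` holds per epoch and class.
#' Only the boosted kinds support attribution.
#'
#' @param model a [TrainedModel-class] of kind `"lightgbm"` or
#'   `"lightgbm_1eeg"`.
#' @param features feature matrix or `SummarizedExperiment`.
#' @return a [ShapAttribution-class].
#' @export
computeShap <- function(model, features) {
  if (!model@kind %in% c("lightgbm", "lightgbm_1eeg"))
    stop("SHAP attribution is only supported for the gradient-boosted ",
         "model kinds, not '", model@kind, "'", call. = FALSE)
  m <- .alignFeatures(model, .featureMatrixOnly(features))
  ctr <- stats::predict(model@fit, m, predcontrib = TRUE,
                        iterationrange = c(1L, model@nRounds))
  p <- ncol(m)
  vals <- ctr[, , seq_len(p), drop = FALSE]
  dimnames(vals) <- list(NULL, STAGE_NAMES, model@schemaNames)
  base <- ctr[, , p + 1L]
  if (is.null(dim(base))) base <- matrix(base, nrow = nrow(m))
  colnames(base) <- STAGE_NAMES
  new("ShapAttribution", values = vals, baseValues = base,
      featureNames = model@schemaNames, classOrder = c(1L, 2L, 3L))
}

#' Global SHAP summary
#'
#' Mean absolute attribution per feature and class over all epochs — the
#' global importance ranking used to inspect what drives each stage's
#' scores (EMG amplitude for Wake, delta power for NREM, theta/delta for
#' REM in typical recordings).
#'
#' @param shap a [ShapAttribution-class].
#' @return numeric features x 3 matrix of mean absolute contributions,
#'   columns Wake, NREM, REM.
#' @export
shapSummary <- function(shap) {
  out <- apply(abs(shap@values), c(3L, 2L), mean)
  dimnames(out) <- list(shap@featureNames, STAGE_NAMES)
  out
}

#' Export SHAP values as a long-format table
#'
#' @param shap a [ShapAttribution-class].
#' @param epochIndices optional epoch indices for the first column
#'   (default 0-based sequence).
#' @return data.frame with columns `epoch_index`, `class`, `feature`,
#'   `value` plus the per-class `base_value`.
#' @export
shapLongFormat <- function(shap, epochIndices = NULL) {
  n <- dim(shap@values)[1]; p <- length(shap@featureNames)
  if (is.null(epochIndices)) epochIndices <- seq_len(n) - 1L
  data.frame(
    epoch_index = rep(epochIndices, times = 3L * p),
    class = rep(rep(STAGE_NAMES, each = n), times = p),
    feature = rep(shap@featureNames, each = 3L * n),
    value = as.vector(shap@values),
    base_value = rep(as.vector(shap@baseValues), times = p),
    stringsAsFactors = FALSE)
}

setMethod("show", "ShapAttribution", function(object) {
  d <- dim(object@values)
  cat(sprintf("ShapAttribution: %d epochs x %d classes x %d features\n",
              d[1], d[2], d[3]))
})
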