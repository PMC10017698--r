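## Classifiers: multinomial ridge logistic regression, random forest, and
## the gradient-boosted tree model (leaf-wise growth, 100 leaves, learning
## rate 0.01, up to 1e5 rounds with early stopping on an inner 80/20
## validation split), all over the canonical epoch feature matrix.

# evaluate expr under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.featureMatrixOnly <- function(x) {
  if (is(x, "SummarizedExperiment")) featureValues(x) else as.matrix(x)
}

.featureInput <- function(x, labels = NULL) {
  m <- .featureMatrixOnly(x)
  if (is(x, "SummarizedExperiment") && is.null(labels))
    labels <- featureStages(x)
  y <- if (is.null(labels)) NULL else as.integer(.asStageVector(labels))
  if (!is.null(y)) {
    .stopifnot1(length(y) == nrow(m), "one label per epoch is required")
    .stopifnot1(!anyNA(y) && all(y %in% 1:3),
                "labels must be stage codes 1, 2, 3")
    .stopifnot1(length(unique(y)) >= 2L,
                "training labels contain a single class")
  }
  list(x = m, y = y)
}

.newModel <- function(kind, fit, featureNames, nRounds, meta) {
  new("TrainedModel", kind = kind, fit = fit,
      schemaFingerprint = schemaFingerprint(featureNames),
      schemaNames = featureNames,
      nRounds = as.integer(nRounds), classOrder = c(1L, 2L, 3L),
      trainingMeta = meta)
}

#' Subject-grouped train/test split
#'
#' Partitions subjects (not epochs) into train and test sides, so that all
#' recordings of a subject fall on one side and the test set is never
#' contaminated by subject-specific patterns.
#'
#' @param subjects character vector of subject ids (duplicates allowed; the
#'   unique set is partitioned). At least 2 unique subjects required.
#' @param testFraction fraction of subjects assigned to the test side
#'   (default 0.125, rounded to at least one subject per side).
#' @param seed RNG seed (default 0).
#' @return list with character vectors `train` and `test` (disjoint).
#' @export
splitBySubject <- function(subjects, testFraction = 0.125, seed = 0) {
  u <- unique(as.character(subjects))
  .stopifnot1(length(u) >= 2L, "at least two subjects are required")
  nTest <- min(length(u) - 1L, max(1L, round(length(u) * testFraction)))
  test <- .withSeed(seed, sample(u, nTest))
  list(train = setdiff(u, test), test = test)
}

#' Fit the multinomial logistic regression baseline
#'
#' L2-penalized (ridge) multinomial logistic regression with inverse
#' regularization strength 1 (penalty `1/(2n) * ||w||^2` on the mean
#' log-loss scale), intercept included, convergence tolerance `1e-4`, at
#' most 10,000 iterations, features unstandardized.
#'
#' @param x feature matrix (epochs x features) or a `SummarizedExperiment`
#'   from [extractFeatures()].
#' @param labels stage codes (taken from `colData(x)$stage` when `x` is a
#'   `SummarizedExperiment`).
#' @param seed RNG seed recorded in the metadata (the fit is deterministic).
#' @return a [TrainedModel-class] of kind `"logreg"`.
#' @export
fitLogreg <- function(x, labels = NULL, seed = 0) {
  inp <- .featureInput(x, labels)
  fit <- glmnet::glmnet(inp$x, factor(inp$y, 1:3), family = "multinomial",
                        alpha = 0, lambda = 1 / nrow(inp$x),
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-4, maxit = 10000)
  .newModel("logreg", fit, colnames(inp$x), NA_integer_,
            list(seed = seed, n_train = nrow(inp$x)))
}

#' Fit the random forest baseline
#'
#' 100 trees, Gini impurity, unlimited depth, minimum node size 1, bootstrap
#' resampling.
#'
#' @inheritParams fitLogreg
#' @param seed RNG seed for the bootstrap/feature subsampling (default 0).
#' @return a [TrainedModel-class] of kind `"random_forest"`.
#' @export
fitRandomForest <- function(x, labels = NULL, seed = 0) {
  inp <- .featureInput(x, labels)
  fit <- .withSeed(seed,
    randomForest::randomForest(x = inp$x, y = factor(inp$y, 1:3),
                               ntree = 100, nodesize = 1, replace = TRUE))
  .newModel("random_forest", fit, colnames(inp$x), NA_integer_,
            list(seed = seed, n_train = nrow(inp$x)))
}

#' Fit the gradient-boosted tree model
#'
#' Leaf-wise gradient-boosted decision trees with 100 leaves per tree,
#' learning rate 0.01, up to 100,000 boosting rounds, and early stopping
#' after 500 rounds without improvement of the multiclass log-loss on an
#' inner validation split (a random 20% of the training epochs; the
#' remaining 80% fit the trees). The number of rounds actually used is
#' recorded on the model.
#'
#' @inheritParams fitLogreg
#' @param seed RNG seed for the inner split and tree construction.
#' @param kind `"lightgbm"` (two-EEG feature set) or `"lightgbm_1eeg"`;
#'   inferred from the schema variant when `x` is a `SummarizedExperiment`.
#' @param innerFitFraction fraction of training epochs used to fit (default
#'   0.8; the rest validate early stopping).
#' @param nRounds,earlyStoppingRounds,numLeaves,learningRate boosting
#'   hyperparameters.
#' @param nthread OpenMP threads (default 1, for determinism).
#' @return a [TrainedModel-class] with `@nRounds` set to the best round.
#' @export
fitGBM <- function(x, labels = NULL, seed = 0, kind = NULL,
                   innerFitFraction = 0.8, nRounds = 100000L,
                   earlyStoppingRounds = 500L, numLeaves = 100L,
                   learningRate = 0.01, nthread = 1L) {
  if (is.null(kind)) {
    kind <- "lightgbm"
    if (is(x, "SummarizedExperiment")) {
      sc <- S4Vectors::metadata(x)$schema
      if (!is.null(sc) && sc@variant == "one_eeg") kind <- "lightgbm_1eeg"
    }
  }
  .stopifnot1(kind %in% c("lightgbm", "lightgbm_1eeg"),
              "kind must be 'lightgbm' or 'lightgbm_1eeg'")
  inp <- .featureInput(x, labels)
  n <- nrow(inp$x)
  .stopifnot1(n >= 10L, "too few epochs (", n, ") for the inner 80/20 split")
  fitIdx <- .withSeed(seed, sample(n, floor(innerFitFraction * n)))
  dfit <- xgboost::xgb.DMatrix(inp$x[fitIdx, , drop = FALSE],
                               label = inp$y[fitIdx] - 1L)
  dval <- xgboost::xgb.DMatrix(inp$x[-fitIdx, , drop = FALSE],
                               label = inp$y[-fitIdx] - 1L)
  params <- list(objective = "multi:softprob", num_class = 3L,
                 eta = learningRate, max_leaves = numLeaves,
                 grow_policy = "lossguide", max_depth = 0L,
                 tree_method = "hist", eval_metric = "mlogloss",
                 nthread = nthread, seed = seed)
  fit <- xgboost::xgb.train(params, dfit, nrounds = nRounds,
                            evals = list(valid = dval),
                            early_stopping_rounds = earlyStoppingRounds,
                            verbose = 0)
  best <- as.integer(xgboost::xgb.attr(fit, "best_iteration"))
  if (!length(best) || is.na(best)) best <- nRounds
  evalLog <- as.data.frame(attributes(fit)$evaluation_log)
  .newModel(kind, fit, colnames(inp$x), best,
            list(seed = seed, n_train = n, n_inner_fit = length(fitIdx),
                 n_inner_valid = n - length(fitIdx),
                 params = params, best_score =
                   as.numeric(xgboost::xgb.attr(fit, "best_score")),
                 evaluation_log = evalLog))
}

# align a feature matrix to a model's schema: reorder name-keyed columns,
# refuse genuinely different schemas naming both fingerprints
.alignFeatures <- function(model, m) {
  if (identical(colnames(m), model@schemaNames)) return(m)
  if (!is.null(colnames(m)) && setequal(colnames(m), model@schemaNames))
    return(m[, model@schemaNames, drop = FALSE])
  stop("feature schema mismatch: model was trained on fingerprint ",
       model@schemaFingerprint, " (", length(model@schemaNames),
       " features), input has fingerprint ",
       schemaFingerprint(colnames(m)), " (", ncol(m), " features)",
       call. = FALSE)
}

#' Per-epoch class probabilities
#'
#' @param model a [TrainedModel-class].
#' @param features feature matrix or `SummarizedExperiment`; the feature
#'   names must match the model's schema (name-keyed column reordering is
#'   applied automatically, anything else is refused).
#' @return numeric epochs x 3 matrix, columns Wake, NREM, REM, rows summing
#'   to 1.
#' @export
predictStageProbs <- function(model, features) {
  m <- .alignFeatures(model, .featureMatrixOnly(features))
  p <- switch(model@kind,
    logreg = {
      pr <- stats::predict(model@fit, m, type = "response")
      matrix(pr, nrow(m), 3L)
    },
    random_forest = {
      unname(stats::predict(model@fit, m, type = "prob"))
    },
    {
      stats::predict(model@fit, m,
                     iterationrange = c(1L, model@nRounds))
    })
  p <- p / rowSums(p)   # exact simplex normalization in double precision
  colnames(p) <- STAGE_NAMES
  p
}

#' Score sleep stages for a feature matrix
#'
#' Per-epoch argmax of the class probabilities; no temporal smoothing or
#' context is applied, so predictions are independent across epochs.
#'
#' @inheritParams predictStageProbs
#' @param epochLengthS epoch length stored on the returned hypnogram; taken
#'   from the feature metadata when available.
#' @return a [Hypnogram-class] with codes 1 (Wake), 2 (NREM), 3 (REM).
#' @export
predictStages <- function(model, features, epochLengthS = NULL) {
  if (is.null(epochLengthS)) {
    epochLengthS <- 10
    if (is(features, "SummarizedExperiment")) {
      el <- S4Vectors::metadata(features)$epochLengthS
      if (!is.null(el)) epochLengthS <- el
    }
  }
  p <- predictStageProbs(model, features)
  Hypnogram(max.col(p, ties.method = "first"), epochLength = epochLengthS)
}

#' Save / load a trained model archive
#'
#' Single-file archive (RDS) containing the model kind, schema fingerprint
#' and names, rounds used, training metadata, package version, and the
#' fitted object (boosted models are stored as a portable raw booster dump).
#'
#' @param model a [TrainedModel-class].
#' @param path archive path.
#' @return `saveModel` returns `path` invisibly; `loadModel` the restored
#'   [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  payload <- if (model@kind %in% c("lightgbm", "lightgbm_1eeg"))
    xgboost::xgb.save.raw(model@fit) else model@fit
  saveRDS(list(format = 1L,
               package_version = as.character(utils::packageVersion("sleepscoreR")),
               kind = model@kind, fingerprint = model@schemaFingerprint,
               schemaNames = model@schemaNames, nRounds = model@nRounds,
               classOrder = model@classOrder, meta = model@trainingMeta,
               payload = payload),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  fit <- if (obj$kind %in% c("lightgbm", "lightgbm_1eeg"))
    xgboost::xgb.load.raw(obj$payload) else obj$payload
  new("TrainedModel", kind = obj$kind, fit = fit,
      schemaFingerprint = obj$fingerprint, schemaNames = obj$schemaNames,
      nRounds = obj$nRounds, classOrder = obj$classOrder,
      trainingMeta = obj$meta)
}
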