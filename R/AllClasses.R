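#' @import methods
NULL

STAGE_CODES <- c(Wake = 1L, NREM = 2L, REM = 3L)
STAGE_NAMES <- names(STAGE_CODES)

#' Multichannel sleep EEG/EMG recording
#'
#' Container for a single polysomnography recording: one or two EEG channels
#' plus exactly one EMG channel, sampled at a common rate, with subject and
#' light/dark-cycle metadata. Amplitudes are stored in microvolts.
#'
#' @slot recordingId character(1) recording identifier.
#' @slot subjectId character(1) subject (animal) identifier.
#' @slot cycle one of `"light"`, `"dark"`, `"unknown"`.
#' @slot samplingRate numeric(1) sampling rate in Hz, shared by all channels.
#' @slot signals numeric matrix, samples x channels, in microvolts.
#' @slot channelRoles character vector of roles, one per column of `signals`;
#'   valid roles are `"EEG1"` (parietal), `"EEG2"` (frontal) and `"EMG"`.
#' @slot channelLabels character vector of the original channel labels.
#'
#' @seealso [readEDF()], [synthRecording()]
#' @export
setClass("SleepRecording",
  representation(
    recordingId   = "character",
    subjectId     = "character",
    cycle         = "character",
    samplingRate  = "numeric",
    signals       = "matrix",
    channelRoles  = "character",
    channelLabels = "character"
  )
)

setValidity("SleepRecording", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!object@cycle %in% c("light", "dark", "unknown"))
    msg <- c(msg, "cycle must be 'light', 'dark' or 'unknown'")
  nch <- ncol(object@signals)
  if (length(object@channelRoles) != nch)
    msg <- c(msg, "one channel role per signal column required")
  if (!all(object@channelRoles %in% c("EEG1", "EEG2", "EMG")))
    msg <- c(msg, "channel roles must be among 'EEG1', 'EEG2', 'EMG'")
  if (sum(object@channelRoles == "EMG") != 1L)
    msg <- c(msg, "exactly one EMG channel is required")
  nEEG <- sum(object@channelRoles %in% c("EEG1", "EEG2"))
  if (nEEG < 1L || nEEG > 2L)
    msg <- c(msg, "one or two EEG channels are required")
  if (anyDuplicated(object@channelRoles))
    msg <- c(msg, "channel roles must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SleepRecording
#'
#' @param signals numeric matrix, samples x channels, microvolts.
#' @param samplingRate sampling rate in Hz.
#' @param channelRoles character vector of roles (`"EEG1"`, `"EEG2"`, `"EMG"`)
#'   matching the columns of `signals`.
#' @param recordingId,subjectId identifiers.
#' @param cycle `"light"`, `"dark"` or `"unknown"`.
#' @param channelLabels original channel labels; defaults to the roles.
#' @return A [SleepRecording-class] object.
#' @export
SleepRecording <- function(signals, samplingRate, channelRoles,
                           recordingId = "rec", subjectId = "subj",
                           cycle = "unknown", channelLabels = channelRoles) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  colnames(signals) <- channelRoles
  new("SleepRecording",
      recordingId = as.character(recordingId),
      subjectId = as.character(subjectId),
      cycle = cycle, samplingRate = as.numeric(samplingRate),
      signals = signals, channelRoles = channelRoles,
      channelLabels = channelLabels)
}

#' Per-epoch sleep stage sequence
#'
#' Stage labels for consecutive fixed-length epochs, with the standard rodent
#' coding Wake = 1, NREM = 2, REM = 3.
#'
#' @slot stages integer vector of stage codes in `{1, 2, 3}`.
#' @slot epochLength numeric(1) epoch length in seconds.
#' @export
setClass("Hypnogram",
  representation(stages = "integer", epochLength = "numeric"))

setValidity("Hypnogram", function(object) {
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    return("epochLength must be a single positive number")
  if (length(object@stages) && !all(object@stages %in% 1:3))
    return("stage codes must be 1 (Wake), 2 (NREM) or 3 (REM)")
  TRUE
})

#' Construct a Hypnogram
#'
#' @param stages integer vector of stage codes (1 = Wake, 2 = NREM, 3 = REM).
#' @param epochLength epoch length in seconds (default 10).
#' @return A [Hypnogram-class] object.
#' @export
Hypnogram <- function(stages, epochLength = 10) {
  new("Hypnogram", stages = as.integer(stages),
      epochLength = as.numeric(epochLength))
}

#' Ordered, named feature space for the epoch feature vector
#'
#' @slot variant `"two_eeg"` (291 features) or `"one_eeg"` (153 features).
#' @slot entries character vector of canonical feature names, in extraction
#'   order. Each name encodes channel role, domain, band (or broadband),
#'   statistic and normalization.
#' @export
setClass("FeatureSchema",
  representation(variant = "character", entries = "character"))

setValidity("FeatureSchema", function(object) {
  if (!object@variant %in% c("two_eeg", "one_eeg"))
    return("variant must be 'two_eeg' or 'one_eeg'")
  want <- if (object@variant == "two_eeg") 291L else 153L
  if (length(object@entries) != want)
    return(sprintf("variant '%s' requires %d entries, got %d",
                   object@variant, want, length(object@entries)))
  if (anyDuplicated(object@entries))
    return("feature names must be unique")
  TRUE
})

#' Fitted sleep-stage classifier
#'
#' Wraps a fitted model together with the fingerprint of the feature schema
#' it was trained on, so that prediction can refuse mismatched feature
#' matrices, plus training metadata.
#'
#' @slot kind one of `"logreg"`, `"random_forest"`, `"lightgbm"`,
#'   `"lightgbm_1eeg"` (the latter two are gradient-boosted tree models).
#' @slot fit the underlying fitted object.
#' @slot schemaFingerprint character(1) hash of the ordered feature names.
#' @slot schemaNames the ordered feature names used in training.
#' @slot nRounds integer(1) boosting rounds actually used (NA for
#'   non-boosted kinds).
#' @slot classOrder fixed stage code order `c(1L, 2L, 3L)`.
#' @slot trainingMeta list of split sizes, seed and hyperparameters.
#' @export
setClass("TrainedModel",
  representation(
    kind = "character", fit = "ANY",
    schemaFingerprint = "character", schemaNames = "character",
    nRounds = "integer", classOrder = "integer", trainingMeta = "list"))

setValidity("TrainedModel", function(object) {
  if (!object@kind %in% c("logreg", "random_forest", "lightgbm",
                          "lightgbm_1eeg"))
    return("unknown model kind")
  if (!identical(object@classOrder, c(1L, 2L, 3L)))
    return("classOrder must be 1, 2, 3 (Wake, NREM, REM)")
  TRUE
})

#' Per-epoch additive (SHAP) feature attributions
#'
#' For each epoch and each stage class, an additive decomposition of the
#' model's margin score over the features: for every epoch/class,
#' `baseValues + sum(values[epoch, class, ])` equals the model margin.
#'
#' @slot values numeric array `epochs x classes x features`.
#' @slot baseValues numeric matrix `epochs x classes` of expected margins.
#' @slot featureNames character vector of feature names (third dimension).
#' @slot classOrder stage code order of the second dimension.
#' @export
setClass("ShapAttribution",
  representation(values = "array", baseValues = "matrix",
                 featureNames = "character", classOrder = "integer"))

## ---- basic accessors ----

#' @describeIn SleepRecording-class number of samples per channel
#' @param x,object a `SleepRecording`
#' @export
setMethod("length", "SleepRecording", function(x) nrow(x@signals))

#' Accessors for SleepRecording
#'
#' @param rec a [SleepRecording-class].
#' @return `samplingRate()` the rate in Hz; `channelRoles()` the role vector;
#'   `signalMatrix()` the samples x channels microvolt matrix;
#'   `recordingDuration()` the duration in seconds.
#' @export
samplingRate <- function(rec) rec@samplingRate

#' @rdname samplingRate
#' @export
channelRoles <- function(rec) rec@channelRoles

#' @rdname samplingRate
#' @export
signalMatrix <- function(rec) rec@signals

#' @rdname samplingRate
#' @export
recordingDuration <- function(rec) nrow(rec@signals) / rec@samplingRate

#' Extract one channel by role
#' @param rec a [SleepRecording-class].
#' @param role `"EEG1"`, `"EEG2"` or `"EMG"`.
#' @return numeric vector of samples in microvolts.
#' @export
channelSignal <- function(rec, role) {
  i <- match(role, rec@channelRoles)
  if (is.na(i)) stop("recording has no channel with role '", role, "'")
  rec@signals[, i]
}

#' @rdname Hypnogram
#' @param h a `Hypnogram`.
#' @export
stageCodes <- function(h) h@stages

#' @rdname Hypnogram
#' @export
epochLength <- function(h) h@epochLength

setMethod("length", "Hypnogram", function(x) length(x@stages))

#' @rdname FeatureSchema-class
#' @param schema a `FeatureSchema`.
#' @export
schemaEntries <- function(schema) schema@entries

#' @rdname FeatureSchema-class
#' @export
schemaVariant <- function(schema) schema@variant

setMethod("show", "SleepRecording", function(object) {
  cat(sprintf(
    "SleepRecording '%s' (subject '%s', %s cycle)\n  %d channels [%s], %.6g Hz, %.1f s\n",
    object@recordingId, object@subjectId, object@cycle,
    ncol(object@signals), paste(object@channelRoles, collapse = ", "),
    object@samplingRate, nrow(object@signals) / object@samplingRate))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- tabulate(object@stages, 3L)
  cat(sprintf(
    "Hypnogram: %d epochs of %g s (Wake %d, NREM %d, REM %d)\n",
    length(object@stages), object@epochLength, tab[1], tab[2], tab[3]))
})

setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf("FeatureSchema '%s': %d features\n",
              object@variant, length(object@entries)))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel kind='%s', %s features, fingerprint %s",
              object@kind, length(object@schemaNames),
              object@schemaFingerprint))
  if (!is.na(object@nRounds))
    cat(sprintf(", %d boosting rounds", object@nRounds))
  cat("\n")
})
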