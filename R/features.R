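#' The five raw time-domain statistics of an epoch
#'
#' Mean, median, maximum and (population) standard deviation of the absolute
#' amplitude, and the root-mean-square amplitude, all in microvolts.
#'
#' @param x numeric vector of epoch samples (microvolts), non-empty.
#' @return named numeric(5): `mean_abs`, `median_abs`, `max_abs`, `std_abs`,
#'   `rms`.
#' @export
timeStats <- function(x) {
  .stopifnot1(length(x) > 0, "empty epoch")
  a <- abs(x)
  c(mean_abs = mean(a), median_abs = stats::median(a), max_abs = max(a),
    std_abs = sqrt(mean(a^2) - mean(a)^2), rms = sqrt(mean(x^2)))
}

# vectorized over epochs: em is a samples x epochs matrix -> epochs x 5
.timeStatsMatrix <- function(em) {
  a <- abs(em)
  m1 <- colMeans(a)
  m2 <- colMeans(a^2)
  cbind(mean_abs = m1,
        median_abs = apply(a, 2L, stats::median),
        max_abs = apply(a, 2L, max),
        std_abs = sqrt(pmax(m2 - m1^2, 0)),
        rms = sqrt(colMeans(em^2)))
}

#' Spectral band powers of an epoch
#'
#' Single-segment FFT periodogram power summed over each band's half-open
#' frequency range `[low, high)`, scaled as `(2/n^2) * sum(|X_k|^2)` so the
#' value is the band's contribution to the signal's mean square (microvolt
#' squared) and is comparable across sampling rates for a fixed epoch
#' duration.
#'
#' @param x numeric vector of epoch samples.
#' @param rate sampling rate in Hz; the Nyquist frequency must exceed the
#'   highest band edge.
#' @param bands band table as from [bandDefinitions()].
#' @return named numeric vector of non-negative powers, one per band.
#' @export
bandPowers <- function(x, rate, bands = bandDefinitions()) {
  drop(.bandPowersMatrix(matrix(x, ncol = 1), rate, bands))
}

.bandPowersMatrix <- function(em, rate, bands) {
  .stopifnot1(rate / 2 > max(bands$high),
              "Nyquist frequency ", rate / 2, " Hz is below the ",
              max(bands$high), " Hz band edge")
  n <- nrow(em)
  .stopifnot1(n >= rate / min(bands$low),
              "epoch shorter than one period of the slowest band")
  P <- Mod(stats::mvfft(em))^2
  f <- (seq_len(n) - 1) * rate / n
  out <- matrix(0, ncol(em), nrow(bands),
                dimnames = list(NULL, bands$name))
  half <- f <= rate / 2
  for (b in seq_len(nrow(bands))) {
    idx <- which(half & f >= bands$low[b] & f < bands$high[b])
    out[, b] <- (2 / n^2) * colSums(P[idx, , drop = FALSE])
  }
  out
}

#' Band-to-delta power ratios
#'
#' Theta/delta, alpha/delta, sigma/delta, beta/delta and low gamma/delta.
#' The delta denominator is floored at `1e-12` so degenerate (silent) epochs
#' stay finite.
#'
#' @param powers named band-power vector from [bandPowers()] (or a matrix
#'   with one row per epoch).
#' @return named numeric(5) of ratios (or an epochs x 5 matrix).
#' @export
bandRatios <- function(powers) {
  if (is.matrix(powers)) {
    d <- .guardDenominator(powers[, "delta"])
    out <- powers[, c("theta", "alpha", "sigma", "beta", "lowgamma"),
                  drop = FALSE] / d
    colnames(out) <- paste0(colnames(out), "_delta_ratio")
    return(out)
  }
  r <- powers[c("theta", "alpha", "sigma", "beta", "lowgamma")] /
    .guardDenominator(powers[["delta"]])
  names(r) <- paste0(names(r), "_delta_ratio")
  r
}

#' Time statistics of a band-filtered epoch
#'
#' The five raw time-domain statistics computed after zero-phase FIR
#' bandpass filtering of the epoch to one canonical band.
#'
#' @param x numeric vector of epoch samples.
#' @param rate sampling rate in Hz.
#' @param band one row of [bandDefinitions()] (or a list with `low`, `high`).
#' @return named numeric(5) as [timeStats()].
#' @export
bandFilteredStats <- function(x, rate, band) {
  .stopifnot1(rate / 2 > band$high,
              "Nyquist frequency below the band's upper edge")
  timeStats(firFilter(x, designFIR(rate, band$low, band$high)))
}

#' Per-recording normalization of raw feature values
#'
#' Divides each epoch's raw feature value by the per-recording mean and by
#' the per-recording median of that feature, yielding two normalized values
#' per raw value. This absorbs inter-recording amplitude scale differences:
#' scaling a whole recording leaves every normalized feature unchanged.
#' Denominators are floored at `1e-12`.
#'
#' @param values numeric vector (or epochs x features matrix) of raw values.
#' @param recordingIds grouping vector, one entry per epoch.
#' @return list with elements `mean_normalized` and `median_normalized`,
#'   each the same shape as `values`.
#' @export
normalizePerRecording <- function(values, recordingIds) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  .stopifnot1(length(recordingIds) == nrow(v),
              "one recording id per epoch is required")
  outM <- v; outMd <- v
  for (g in split(seq_len(nrow(v)), recordingIds)) {
    mu <- .guardDenominator(colMeans(v[g, , drop = FALSE]))
    md <- .guardDenominator(apply(v[g, , drop = FALSE], 2L, stats::median))
    outM[g, ] <- sweep(v[g, , drop = FALSE], 2L, mu, "/")
    outMd[g, ] <- sweep(v[g, , drop = FALSE], 2L, md, "/")
  }
  if (!is.matrix(values)) {
    outM <- drop(outM); outMd <- drop(outMd)
  }
  list(mean_normalized = outM, median_normalized = outMd)
}

# interleave raw / mean-normalized / median-normalized columns; the whole
# feature matrix here always belongs to a single recording
.expandNormalize <- function(raw) {
  k <- nrow(raw)
  out <- matrix(0, k, 3L * ncol(raw))
  mu <- .guardDenominator(colMeans(raw))
  md <- .guardDenominator(apply(raw, 2L, stats::median))
  out[, seq(1L, by = 3L, length.out = ncol(raw))] <- raw
  out[, seq(2L, by = 3L, length.out = ncol(raw))] <- sweep(raw, 2L, mu, "/")
  out[, seq(3L, by = 3L, length.out = ncol(raw))] <- sweep(raw, 2L, md, "/")
  out
}

# all 46 raw features of one EEG channel (5 time + 6 power + 5 ratio +
# 30 band-filtered time); x is the already 1-40 Hz filtered channel
.rawEEGFeatures <- function(x, rate, nPer, bands, firs) {
  em <- .epochMatrix(x, nPer)
  ts <- .timeStatsMatrix(em)
  bp <- .bandPowersMatrix(em, rate, bands)
  br <- bandRatios(bp)
  filt <- .firFilterMulti(x, firs)
  fs <- do.call(cbind, lapply(filt, function(y)
    .timeStatsMatrix(.epochMatrix(y, nPer))))
  cbind(ts, bp, br, fs)
}

#' Extract the per-epoch feature matrix of a recording
#'
#' Applies the 1-40 Hz zero-phase bandpass, segments the recording into
#' epochs (trailing partial epoch dropped), and computes the canonical
#' feature vector per epoch: per EEG channel 15 broadband time statistics,
#' 18 band powers, 15 band/delta ratios and 90 FIR band-filtered time
#' statistics (raw plus per-recording mean- and median-normalized versions
#' throughout), and 15 EMG time statistics. Band-filtered statistics are
#' computed by filtering the whole channel once per band and then
#' segmenting, which avoids per-epoch filter edge effects.
#'
#' @param rec a [SleepRecording-class] with the roles the variant requires.
#' @param variant `"two_eeg"` (291 features; requires EEG1, EEG2 and EMG) or
#'   `"one_eeg"` (153 features; one EEG channel and EMG).
#' @param eegRole for `"one_eeg"`, which physical channel to use
#'   (`"EEG1"` parietal or `"EEG2"` frontal; default the first EEG present).
#' @param epochLengthS epoch length in seconds (default 10).
#' @param stages optional [Hypnogram-class] (or integer vector) of reference
#'   stage labels stored alongside the epochs.
#' @return a [SummarizedExperiment::SummarizedExperiment] with features as
#'   rows (assay `"features"`), epochs as columns, epoch keys
#'   (`recording_id`, `subject_id`, `epoch_index`, `cycle`, optional `stage`)
#'   in `colData`, and the [FeatureSchema-class] plus its fingerprint in
#'   `metadata`.
#' @export
extractFeatures <- function(rec, variant = c("two_eeg", "one_eeg"),
                            eegRole = NULL, epochLengthS = 10,
                            stages = NULL) {
  variant <- match.arg(variant)
  roles <- rec@channelRoles
  if (variant == "two_eeg") {
    .stopifnot1(all(c("EEG1", "EEG2", "EMG") %in% roles),
                "variant 'two_eeg' requires EEG1, EEG2 and EMG channels")
    eegCols <- list(EEG1 = "EEG1", EEG2 = "EEG2")
  } else {
    if (is.null(eegRole))
      eegRole <- intersect(c("EEG1", "EEG2"), roles)[1]
    .stopifnot1(eegRole %in% roles,
                "requested EEG role '", eegRole, "' not present")
    eegCols <- list(EEG = eegRole)
  }

  rate <- rec@samplingRate
  filtered <- preprocessRecording(rec)
  nPer <- as.integer(round(epochLengthS * rate))
  k <- nrow(filtered@signals) %/% nPer
  .stopifnot1(k >= 1L, "recording shorter than one epoch")

  bands <- bandDefinitions()
  firs <- lapply(seq_len(nrow(bands)), function(b)
    designFIR(rate, bands$low[b], bands$high[b]))

  blocks <- lapply(eegCols, function(role)
    .expandNormalize(.rawEEGFeatures(channelSignal(filtered, role),
                                     rate, nPer, bands, firs)))
  emgRaw <- .timeStatsMatrix(.epochMatrix(channelSignal(filtered, "EMG"),
                                          nPer))
  mat <- cbind(do.call(cbind, blocks), .expandNormalize(emgRaw))

  schema <- featureSchema(variant)
  colnames(mat) <- schema@entries
  .stopifnot1(all(is.finite(mat)), "non-finite feature values produced")

  stageVec <- rep(NA_integer_, k)
  if (!is.null(stages)) {
    s <- if (is(stages, "Hypnogram")) stages@stages else as.integer(stages)
    .stopifnot1(length(s) >= k, "fewer stage labels (", length(s),
                ") than epochs (", k, ")")
    stageVec <- s[seq_len(k)]
  }
  cd <- S4Vectors::DataFrame(
    recording_id = rec@recordingId, subject_id = rec@subjectId,
    epoch_index = seq_len(k) - 1L, cycle = rec@cycle, stage = stageVec)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat)), colData = cd,
    metadata = list(schema = schema,
                    fingerprint = schemaFingerprint(schema@entries),
                    samplingRate = rate, epochLengthS = epochLengthS))
}

#' Extract features from a batch of EDF files
#'
#' Reads each EDF (and optionally its hypnogram label file), extracts
#' features, and column-binds the per-recording results into one feature
#' matrix.
#'
#' @param files character vector of EDF paths.
#' @param labelFiles optional character vector of hypnogram txt paths,
#'   parallel to `files`.
#' @param subjectIds,cycles optional overrides, parallel to `files`.
#' @param resampleTo optional target rate in Hz applied before extraction.
#' @param channelMap see [readEDF()].
#' @inheritParams extractFeatures
#' @return a combined `SummarizedExperiment` as from [extractFeatures()].
#' @export
extractBatch <- function(files, labelFiles = NULL,
                         variant = c("two_eeg", "one_eeg"), eegRole = NULL,
                         subjectIds = NULL, cycles = NULL,
                         resampleTo = NULL, epochLengthS = 10,
                         channelMap = defaultChannelMap()) {
  variant <- match.arg(variant)
  ses <- vector("list", length(files))
  for (i in seq_along(files)) {
    rec <- readEDF(files[i], channelMap = channelMap,
                   subjectId = if (!is.null(subjectIds)) subjectIds[i],
                   cycle = if (!is.null(cycles)) cycles[i])
    if (!is.null(resampleTo)) rec <- resampleRecording(rec, resampleTo)
    stages <- if (!is.null(labelFiles))
      readHypnogram(labelFiles[i], epochLengthS)
    ses[[i]] <- extractFeatures(rec, variant, eegRole = eegRole,
                                epochLengthS = epochLengthS,
                                stages = stages)
  }
  do.call(BiocGenerics::cbind, ses)
}

#' Epoch x feature matrix view of an extracted feature set
#'
#' @param se a `SummarizedExperiment` from [extractFeatures()].
#' @return `featureValues()`: numeric epochs x features matrix;
#'   `featureStages()`: integer vector of reference stage codes (NA where
#'   absent).
#' @export
featureValues <- function(se) {
  t(SummarizedExperiment::assay(se, "features"))
}

#' @rdname featureValues
#' @export
featureStages <- function(se) {
  SummarizedExperiment::colData(se)$stage
}
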