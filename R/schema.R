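## Canonical feature schema.
##
## Per EEG channel (138 features):
##   broadband time stats          5 raw x 3 normalizations = 15
##   band powers                   6 raw x 3                = 18
##   band/delta power ratios       5 raw x 3                = 15
##   FIR band-filtered time stats  6 bands x 5 raw x 3      = 90
## EMG (15 features): broadband time stats only.
## Totals: two_eeg = 2 x 138 + 15 = 291; one_eeg = 138 + 15 = 153;
## temporal = 3 x 15 = 45; frequency-domain per EEG channel = 123.
##
## Each raw statistic is followed immediately by its per-recording
## mean-normalized and median-normalized versions ("_raw", "_normmean",
## "_normmedian"), the per-recording normalization that absorbs
## inter-recording amplitude differences.

.TIME_STATS <- c("mean_abs", "median_abs", "max_abs", "std_abs", "rms")
.NORMS <- c("raw", "normmean", "normmedian")

.tripled <- function(base) {
  as.vector(t(outer(base, .NORMS, paste, sep = "_")))
}

.eegChannelNames <- function(ch) {
  bands <- bandDefinitions()$name
  c(.tripled(paste(ch, "time_broadband", .TIME_STATS, sep = "_")),
    .tripled(paste(ch, "freq", bands, "power", sep = "_")),
    .tripled(paste(ch, "freq", bands[-1], "delta_ratio", sep = "_")),
    .tripled(paste(ch, "freq",
                   rep(bands, each = length(.TIME_STATS)), "filt",
                   rep(.TIME_STATS, times = length(bands)), sep = "_")))
}

.emgChannelNames <- function() {
  .tripled(paste("EMG", "time_broadband", .TIME_STATS, sep = "_"))
}

#' The canonical epoch feature schema
#'
#' `"two_eeg"`: 138 features per EEG channel (`EEG1_`, `EEG2_` prefixes) plus
#' 15 EMG time-domain features, 291 in total. `"one_eeg"`: a single
#' channel-agnostic EEG block (`EEG_` prefix, so a model trained on either
#' physical EEG channel applies to the other) plus the 15 EMG features,
#' 153 in total.
#'
#' @param variant `"two_eeg"` or `"one_eeg"`.
#' @return a [FeatureSchema-class].
#' @export
featureSchema <- function(variant = c("two_eeg", "one_eeg")) {
  variant <- match.arg(variant)
  entries <- if (variant == "two_eeg") {
    c(.eegChannelNames("EEG1"), .eegChannelNames("EEG2"), .emgChannelNames())
  } else {
    c(.eegChannelNames("EEG"), .emgChannelNames())
  }
  new("FeatureSchema", variant = variant, entries = entries)
}

#' Printed count summary of a feature schema
#'
#' @param schema a [FeatureSchema-class].
#' @return named integer vector: total, per-EEG-channel, EMG, temporal and
#'   frequency-domain feature counts.
#' @export
schemaCounts <- function(schema) {
  e <- schema@entries
  time <- grepl("_time_", e)
  emg <- startsWith(e, "EMG_")
  eegCh <- unique(sub("_.*$", "", e[!emg]))
  c(total = length(e),
    per_eeg_channel = sum(startsWith(e, paste0(eegCh[1], "_"))),
    emg = sum(emg),
    temporal = sum(time),
    frequency = sum(!time))
}
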