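#' Recording-level quality control
#'
#' Two exclusion criteria, applied to the raw (unfiltered) signals: a
#' recording fails when any EEG channel's absolute amplitude stays below
#' `eegFloor` for at least `lowFractionThreshold` of the samples, or when the
#' EMG channel's absolute amplitude stays below `emgFloor` for at least that
#' fraction. Both comparisons are inclusive ("at least 50% of the time").
#'
#' The default EMG floor is 1 pV (`1e-6` microvolts). A picovolt threshold is
#' physically indistinguishable from requiring a non-dead channel; if you
#' want the EMG criterion to bite on real attenuated signals, set
#' `emgFloor = 1` (microvolt) to mirror the EEG criterion.
#'
#' @param rec a [SleepRecording-class].
#' @param eegFloor EEG amplitude floor in microvolts (default 1).
#' @param emgFloor EMG amplitude floor in microvolts (default `1e-6`, i.e.
#'   1 pV; see Details).
#' @param lowFractionThreshold fraction of low-amplitude samples at or above
#'   which a channel fails (default 0.5).
#' @return data.frame with one row: `recording_id`, one
#'   `low_fraction_<role>` column per channel, `passed`, and a
#'   semicolon-separated `reasons` string (empty when passed).
#' @export
checkQuality <- function(rec, eegFloor = 1, emgFloor = 1e-6,
                         lowFractionThreshold = 0.5) {
  roles <- rec@channelRoles
  floors <- ifelse(roles == "EMG", emgFloor, eegFloor)
  frac <- vapply(seq_along(roles), function(j)
    mean(abs(rec@signals[, j]) < floors[j]), 0)
  names(frac) <- roles
  failed <- frac >= lowFractionThreshold
  reasons <- sprintf(
    "%s amplitude below %g uV for %.1f%% of samples (threshold %g%%)",
    roles[failed], floors[failed], 100 * frac[failed],
    100 * lowFractionThreshold)
  out <- data.frame(recording_id = rec@recordingId,
                    t(frac), passed = !any(failed),
                    reasons = paste(reasons, collapse = "; "),
                    stringsAsFactors = FALSE)
  names(out)[seq_along(roles) + 1L] <- paste0("low_fraction_", roles)
  out
}
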