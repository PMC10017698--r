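#' Canonical EEG frequency bands
#'
#' The six fixed bands used throughout the feature set: delta 1-4, theta 4-8,
#' alpha 8-12, sigma 12-15, beta 15-30 and low gamma 30-40 Hz. Band intervals
#' are treated as half-open `[low, high)` so adjacent bands never share a
#' frequency bin.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
bandDefinitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "sigma", "beta", "lowgamma"),
    low  = c(1, 4, 8, 12, 15, 30),
    high = c(4, 8, 12, 15, 30, 40),
    stringsAsFactors = FALSE)
}

#' Design a linear-phase bandpass FIR filter
#'
#' Hamming-windowed FIR with order chosen for approximately `transition` Hz
#' of transition bandwidth at the given sampling rate (order scales with the
#' rate), matching the resolution needed to separate 1-Hz-wide band edges.
#'
#' @param rate sampling rate in Hz.
#' @param low,high band edges in Hz; `high = NULL` gives a highpass,
#'   `low = 0` a lowpass.
#' @param transition approximate transition bandwidth in Hz (default 1).
#' @return numeric vector of filter coefficients (odd length, linear phase).
#' @export
designFIR <- function(rate, low, high = NULL, transition = 1) {
  .stopifnot1(rate > 0, "rate must be positive")
  ny <- rate / 2
  if (!is.null(high)) .stopifnot1(high < ny,
    "band edge ", high, " Hz requires sampling rate > ", 2 * high, " Hz")
  n <- ceiling(3.3 * rate / transition)
  if (n %% 2L == 1L) n <- n + 1L          # even order -> odd length, type I
  if (low > 0 && !is.null(high)) {
    signal::fir1(n, c(low, high) / ny, type = "pass")
  } else if (low > 0) {
    signal::fir1(n, low / ny, type = "high")
  } else {
    signal::fir1(n, high / ny, type = "low")
  }
}

# Zero-phase FIR filtering via the frequency domain: the signal is padded,
# transformed once, multiplied by |H(f)|^2 (the forward-backward response of
# the linear-phase kernel), and transformed back. Equivalent to filtfilt with
# the same kernel, without the O(n * taps) time-domain cost.
.fftOfPadded <- function(x, M) {
  L <- length(x)
  Nf <- .nextFast(L + 2L * M)
  list(X = stats::fft(c(numeric(M), x, numeric(Nf - L - M))), L = L,
       M = M, Nf = Nf)
}

.firResponseSq <- function(h, Nf) {
  Mod(stats::fft(c(h, numeric(Nf - length(h)))))^2
}

.applyResponse <- function(pad, Hsq) {
  y <- Re(stats::fft(pad$X * Hsq, inverse = TRUE)) / pad$Nf
  y[(pad$M + 1L):(pad$M + pad$L)]
}

#' Zero-phase FIR filtering
#'
#' Applies the filter forward-backward (zero phase, magnitude response
#' squared), implemented in the frequency domain.
#'
#' @param x numeric signal.
#' @param h FIR coefficients from [designFIR()].
#' @return filtered signal, same length as `x`.
#' @export
firFilter <- function(x, h) {
  pad <- .fftOfPadded(x, length(h))
  .applyResponse(pad, .firResponseSq(h, pad$Nf))
}

# Apply several FIR kernels to one signal, reusing a single forward FFT.
# Kernels must share a common max length M for the padding.
.firFilterMulti <- function(x, hs) {
  M <- max(vapply(hs, length, 1L))
  pad <- .fftOfPadded(x, M)
  lapply(hs, function(h) .applyResponse(pad, .firResponseSq(h, pad$Nf)))
}

#' Bandpass-filter all channels of a recording (1-40 Hz by default)
#'
#' The standard preprocessing before feature extraction: a zero-phase 1-40 Hz
#' bandpass on every channel, which also removes 50/60 Hz line noise. Signal
#' length is preserved.
#'
#' @param rec a [SleepRecording-class]; sampling rate must exceed 80 Hz so the
#'   40 Hz edge stays below Nyquist with margin.
#' @param low,high passband edges in Hz.
#' @return a filtered [SleepRecording-class].
#' @export
preprocessRecording <- function(rec, low = 1, high = 40) {
  .stopifnot1(rec@samplingRate > 2 * high,
              "sampling rate must exceed ", 2 * high,
              " Hz for a ", high, " Hz passband edge")
  h <- designFIR(rec@samplingRate, low, high)
  out <- rec
  for (j in seq_len(ncol(rec@signals)))
    out@signals[, j] <- firFilter(rec@signals[, j], h)
  out
}
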