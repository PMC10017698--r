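#' Resample a recording to a lower rate
#'
#' Fourier-domain resampling: each channel's spectrum is truncated at the
#' target Nyquist frequency and inverse-transformed at the new length, so
#' the operation is anti-aliased by construction (content above the new
#' Nyquist is removed exactly, in-band content is untouched). Duration is
#' preserved to within one sample. Only downsampling is supported.
#'
#' @param rec a [SleepRecording-class].
#' @param targetRate target rate in Hz; must satisfy
#'   `100 <= targetRate <= samplingRate(rec)`.
#' @return a resampled [SleepRecording-class].
#' @export
resampleRecording <- function(rec, targetRate) {
  rate <- rec@samplingRate
  .stopifnot1(targetRate <= rate,
              "upsampling requested (", targetRate, " > ", rate,
              " Hz); only downsampling is supported")
  .stopifnot1(targetRate >= 100,
              "target rate below the 100 Hz scoring minimum")
  if (targetRate == rate) return(rec)
  n <- nrow(rec@signals)
  nOut <- as.integer(round(n * targetRate / rate))
  sig <- matrix(0, nOut, ncol(rec@signals))
  for (j in seq_len(ncol(sig)))
    sig[, j] <- .fourierResample(rec@signals[, j], nOut)
  out <- rec
  out@signals <- sig
  colnames(out@signals) <- rec@channelRoles
  out@samplingRate <- as.numeric(targetRate)
  out
}

.fourierResample <- function(x, nOut) {
  n <- length(x)
  X <- stats::fft(x)
  keep <- (min(n, nOut) - 1L) %/% 2L   # strictly below output Nyquist
  Y <- complex(real = numeric(nOut), imaginary = numeric(nOut))
  Y[1] <- X[1]
  if (keep >= 1L) {
    Y[2:(keep + 1L)] <- X[2:(keep + 1L)]
    Y[(nOut - keep + 1L):nOut] <- X[(n - keep + 1L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Segment a recording into fixed-length epochs
#'
#' Epochs tile the recording contiguously from time zero; a trailing partial
#' epoch is discarded.
#'
#' @param rec a [SleepRecording-class].
#' @param epochLengthS epoch length in seconds (default 10).
#' @return data.frame with 0-based `index`, `start_time` (s) and
#'   `samples_per_channel`.
#' @export
segmentEpochs <- function(rec, epochLengthS = 10) {
  nPer <- epochLengthS * rec@samplingRate
  .stopifnot1(abs(nPer - round(nPer)) < 1e-9,
              "epoch length times sampling rate must be an integer")
  nPer <- as.integer(round(nPer))
  k <- nrow(rec@signals) %/% nPer
  .stopifnot1(k >= 1L, "recording shorter than one epoch (",
              nrow(rec@signals) / rec@samplingRate, " s < ", epochLengthS,
              " s)")
  data.frame(index = seq_len(k) - 1L,
             start_time = (seq_len(k) - 1L) * epochLengthS,
             samples_per_channel = nPer)
}

# samples x epochs matrix for one channel (trailing partial epoch dropped)
.epochMatrix <- function(x, nPer) {
  k <- length(x) %/% nPer
  matrix(x[seq_len(k * nPer)], nrow = nPer, ncol = k)
}

#' Read and write hypnogram label files
#'
#' Plain UTF-8 text, one stage code per line (1 = Wake, 2 = NREM, 3 = REM),
#' in epoch order. `readHypnogram(writeHypnogram(h))` is the identity.
#'
#' @param h a [Hypnogram-class].
#' @param path file path.
#' @param epochLengthS epoch length recorded on the object when reading.
#' @return `writeHypnogram` returns `path` invisibly; `readHypnogram`
#'   returns a [Hypnogram-class].
#' @export
writeHypnogram <- function(h, path) {
  writeLines(as.character(h@stages), path)
  invisible(path)
}

#' @rdname writeHypnogram
#' @export
readHypnogram <- function(path, epochLengthS = 10) {
  .stopifnot1(file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path))
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]           # trailing blank lines only
  bad <- which(!lines %in% c("1", "2", "3"))
  if (length(bad))
    stop("invalid stage code '", lines[bad[1]], "' at line ", bad[1],
         " of ", path, " (valid codes: 1, 2, 3)", call. = FALSE)
  Hypnogram(as.integer(lines), epochLength = epochLengthS)
}
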