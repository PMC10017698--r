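## Minimal EDF (16-bit European Data Format) reader/writer for EEG/EMG
## polysomnography. Covers the plain-EDF subset this package needs: integer
## per-record sample counts, one common rate across mapped channels, EDF+
## annotation channels are ignored on read.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width)   # left-justified, space padded
}

.edfNum <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d, width = 1)
    if (nchar(s) <= width) return(.edfPad(s, width))
  }
  stop("cannot format ", x, " into ", width, " EDF header characters")
}

#' Write a recording to an EDF file
#'
#' Plain EDF, 16-bit samples, 1-s data records. Each channel's physical range
#' is set symmetrically from its own amplitude maximum, so quantization error
#' is below `max(abs(x)) / 32767` per channel. A trailing partial second is
#' not written.
#'
#' @param rec a [SleepRecording-class]; the sampling rate must be a whole
#'   number of samples per 1-s record.
#' @param path output file path.
#' @param physicalDim physical dimension string stored per channel
#'   (default `"uV"`; `"mV"`/`"V"` write the amplitudes converted to that
#'   unit, exercising the reader's unit handling).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physicalDim = "uV") {
  rate <- rec@samplingRate
  .stopifnot1(abs(rate - round(rate)) < 1e-9,
              "writeEDF requires an integer sampling rate")
  rate <- as.integer(round(rate))
  ns <- ncol(rec@signals)
  nrec <- nrow(rec@signals) %/% rate
  .stopifnot1(nrec >= 1L, "recording shorter than one 1-s data record")
  unitScale <- switch(physicalDim, uV = 1, mV = 1e-3, V = 1e-6,
                      stop("physicalDim must be 'uV', 'mV' or 'V'"))
  sig <- rec@signals[seq_len(nrec * rate), , drop = FALSE] * unitScale

  physMax <- apply(abs(sig), 2L, max)
  physMax <- ifelse(physMax > 0, signif(physMax * 1.001, 6), 1)
  # digitization must use exactly the value written into the 8-char header
  physMax <- vapply(physMax,
                    function(v) as.numeric(trimws(.edfNum(v))), 0)
  digMin <- -32768L; digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(.edfPad("0", 8))                                   # version
  wr(.edfPad(rec@subjectId, 80))                        # local patient id
  wr(.edfPad(paste0(rec@recordingId, " cycle=", rec@cycle), 80))
  wr(.edfPad("01.01.01", 8)); wr(.edfPad("00.00.00", 8))
  wr(.edfPad(256L * (1L + ns), 8))                      # header bytes
  wr(.edfPad("", 44))                                   # reserved
  wr(.edfPad(nrec, 8)); wr(.edfPad("1", 8)); wr(.edfPad(ns, 4))
  wr(paste0(vapply(rec@channelLabels, .edfPad, "", width = 16), collapse = ""))
  wr(strrep(" ", 80L * ns))                             # transducer
  wr(paste0(rep(.edfPad(physicalDim, 8), ns), collapse = ""))
  wr(paste0(vapply(-physMax, .edfNum, ""), collapse = ""))
  wr(paste0(vapply(physMax, .edfNum, ""), collapse = ""))
  wr(paste0(rep(.edfPad(digMin, 8), ns), collapse = ""))
  wr(paste0(rep(.edfPad(digMax, 8), ns), collapse = ""))
  wr(strrep(" ", 80L * ns))                             # prefiltering
  wr(paste0(rep(.edfPad(rate, 8), ns), collapse = ""))
  wr(strrep(" ", 32L * ns))                             # reserved

  # digital conversion, record-major with channels sequential inside a record
  gain <- (2 * physMax) / (digMax - digMin)
  dig <- matrix(0L, nrow(sig), ns)
  for (j in seq_len(ns)) {
    d <- round((sig[, j] - (-physMax[j])) / gain[j]) + digMin
    dig[, j] <- as.integer(pmin(pmax(d, digMin), digMax))
  }
  out <- integer(nrec * rate * ns)
  for (j in seq_len(ns)) {
    pos <- rep((seq_len(nrec) - 1L) * ns * rate + (j - 1L) * rate,
               each = rate) + seq_len(rate)
    out[pos] <- dig[, j]
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Default channel-role mapping
#'
#' Case-insensitive regular expressions matching EDF channel labels to the
#' roles `EEG1` (parietal), `EEG2` (frontal) and `EMG`.
#'
#' @return named list of regex patterns.
#' @export
defaultChannelMap <- function() {
  list(EEG1 = "^\\s*EEG\\s*1", EEG2 = "^\\s*EEG\\s*2", EMG = "^\\s*EMG")
}

.readEdfHeader <- function(con) {
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    sub("\\s+$", "", s)
  }
  h <- list()
  h$version <- rd(8); h$patient <- rd(80); h$recording <- rd(80)
  h$startdate <- rd(8); h$starttime <- rd(8)
  h$headerBytes <- as.integer(rd(8)); h$reserved <- rd(44)
  h$nRecords <- as.integer(rd(8)); h$recordDuration <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  ns <- h$ns
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  h$labels <- fld(16); h$transducer <- fld(80); h$dim <- fld(8)
  h$physMin <- as.numeric(fld(8)); h$physMax <- as.numeric(fld(8))
  h$digMin <- as.numeric(fld(8)); h$digMax <- as.numeric(fld(8))
  h$prefilter <- fld(80); h$spr <- as.integer(fld(8)); h$sigReserved <- fld(32)
  h
}

.unitToMicrovolt <- function(dim) {
  d <- trimws(dim)
  if (d %in% c("uV", "µV", "μV")) return(1)
  if (d == "mV") return(1e3)
  if (d == "V") return(1e6)
  warning("unknown physical dimension '", d, "'; assuming microvolts",
          call. = FALSE)
  1
}

#' Read an EDF/EDF+ recording
#'
#' Reads the file, maps channel labels to the roles `EEG1`/`EEG2`/`EMG` via
#' regular expressions, and returns the mapped channels as a
#' [SleepRecording-class] with amplitudes converted to microvolts.
#' `EEG2` is optional (single-EEG setups); `EMG` and at least one EEG role
#' are required. EDF+ annotation channels are ignored.
#'
#' @param path EDF file path.
#' @param channelMap named list of case-insensitive regex patterns per role;
#'   see [defaultChannelMap()]. A role whose pattern is `NULL` is skipped.
#' @param recordingId,subjectId,cycle optional overrides; by default parsed
#'   from the EDF header (written by [writeEDF()]) or derived from the file
#'   name.
#' @param minRate minimum acceptable sampling rate in Hz (default 100; the
#'   scorer's feature set is not defined below this).
#' @return a [SleepRecording-class].
#' @export
readEDF <- function(path, channelMap = defaultChannelMap(),
                    recordingId = NULL, subjectId = NULL, cycle = NULL,
                    minRate = 100) {
  .stopifnot1(file.exists(path), "file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .readEdfHeader(con)
  dataLabels <- h$labels
  isAnnot <- grepl("EDF Annotations", dataLabels, fixed = TRUE)

  roles <- intersect(c("EEG1", "EEG2", "EMG"), names(channelMap))
  roles <- roles[!vapply(channelMap[roles], is.null, TRUE)]
  .stopifnot1("EMG" %in% roles, "channelMap must assign the EMG role")
  .stopifnot1(any(c("EEG1", "EEG2") %in% roles),
              "channelMap must assign at least one EEG role")
  idx <- integer(0); mapped <- character(0)
  for (r in roles) {
    hit <- which(grepl(channelMap[[r]], dataLabels, ignore.case = TRUE) &
                   !isAnnot)
    if (length(hit) > 1L)
      stop("channel map for role '", r, "' is ambiguous; matches: ",
           paste(sQuote(dataLabels[hit]), collapse = ", "), call. = FALSE)
    if (length(hit) == 0L) {
      if (r == "EMG")
        stop("no channel matches role '", r, "' (pattern ",
             sQuote(channelMap[[r]]), "); available labels: ",
             paste(sQuote(dataLabels[!isAnnot]), collapse = ", "),
             call. = FALSE)
      next
    }
    idx <- c(idx, hit); mapped <- c(mapped, r)
  }
  .stopifnot1(any(c("EEG1", "EEG2") %in% mapped),
              "no channel matches an EEG role; available labels: ",
              paste(sQuote(dataLabels[!isAnnot]), collapse = ", "))

  spr <- h$spr[idx]
  if (length(unique(spr)) != 1L)
    stop("mapped channels have unequal sampling rates (",
         paste(spr, collapse = ", "), " samples per ", h$recordDuration,
         " s record); a common rate is required", call. = FALSE)
  rate <- spr[1] / h$recordDuration
  .stopifnot1(rate >= minRate, "sampling rate ", rate,
              " Hz is below the minimum of ", minRate, " Hz")

  S <- sum(h$spr)
  raw <- readBin(con, integer(), n = h$nRecords * S, size = 2L,
                 signed = TRUE, endian = "little")
  off <- c(0L, cumsum(h$spr))
  sig <- matrix(0, h$nRecords * spr[1], length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    pos <- rep((seq_len(h$nRecords) - 1L) * S + off[j], each = h$spr[j]) +
      seq_len(h$spr[j])
    d <- raw[pos]
    scale <- (h$physMax[j] - h$physMin[j]) / (h$digMax[j] - h$digMin[j])
    sig[, k] <- (h$physMin[j] + (d - h$digMin[j]) * scale) *
      .unitToMicrovolt(h$dim[j])
  }

  recTxt <- h$recording
  if (is.null(cycle)) {
    cycle <- sub(".*cycle=(light|dark).*", "\\1", recTxt)
    if (!cycle %in% c("light", "dark")) cycle <- "unknown"
  }
  if (is.null(recordingId)) {
    recordingId <- sub(" cycle=.*$", "", recTxt)
    if (!nzchar(recordingId))
      recordingId <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(subjectId))
    subjectId <- if (nzchar(h$patient)) h$patient else recordingId

  SleepRecording(sig, rate, mapped, recordingId = recordingId,
                 subjectId = subjectId, cycle = cycle,
                 channelLabels = dataLabels[idx])
}
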