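## Synthetic mouse sleep EEG/EMG: a semi-Markov hypnogram process with
## stage-specific spectral signatures rendered as band-limited noise, so the
## full scoring pipeline can be exercised without any recorded data.

#' Default stage spectral/amplitude signatures
#'
#' Relative EEG band-power profiles, EEG amplitude scales and EMG amplitude
#' scales per stage, emulating the discriminative structure of rodent sleep:
#' NREM is delta-dominant and high-amplitude, REM is theta-dominant with
#' muscle atonia (lowest EMG), Wake is low-amplitude mixed-spectrum EEG with
#' the highest EMG tone.
#'
#' @param separability in `(0, 1]`: 1 keeps the full contrast between stage
#'   signatures; smaller values shrink every stage's profile and scales
#'   toward the across-stage mean, making stages harder to discriminate
#'   (a difficulty knob for benchmarking).
#' @return list with `bandWeights` (3 x 6 matrix of relative band powers,
#'   rows Wake/NREM/REM summing to 1), `eegScale` and `emgScale` (named
#'   per-stage RMS amplitudes, microvolts) and `noise` (broadband white
#'   noise RMS, microvolts).
#' @export
stageSignatureDefaults <- function(separability = 1) {
  .stopifnot1(separability > 0 && separability <= 1,
              "separability must be in (0, 1]")
  bands <- bandDefinitions()$name
  w <- rbind(
    Wake = c(0.18, 0.30, 0.18, 0.08, 0.16, 0.10),
    NREM = c(0.55, 0.15, 0.10, 0.10, 0.07, 0.03),
    REM  = c(0.12, 0.55, 0.12, 0.06, 0.10, 0.05))
  colnames(w) <- bands
  eeg <- c(Wake = 40, NREM = 80, REM = 50)
  emg <- c(Wake = 40, NREM = 10, REM = 3)
  shrink <- function(m) {
    ctr <- if (is.matrix(m)) rep(colMeans(m), each = nrow(m)) else mean(m)
    ctr + separability * (m - ctr)
  }
  list(bandWeights = shrink(w), eegScale = shrink(eeg),
       emgScale = shrink(emg), noise = 2)
}

#' Default semi-Markov hypnogram process
#'
#' Mean stage dwell times (seconds) and the embedded transition matrix of a
#' fragmented rodent sleep pattern: wake leads into NREM, REM is entered
#' predominantly from NREM, and brief episodes alternate on a minutes
#' timescale. In the dark (active) cycle wake bouts lengthen substantially,
#' shifting stage proportions toward wake, as in mouse actigraphy.
#'
#' @param cycle `"light"` or `"dark"`.
#' @return list with `dwellMean` (named numeric, seconds) and `transition`
#'   (3 x 3 row-stochastic matrix, zero diagonal, rows/cols Wake/NREM/REM).
#' @export
hypnogramProcessDefaults <- function(cycle = c("light", "dark")) {
  cycle <- match.arg(cycle)
  dwell <- c(Wake = if (cycle == "light") 120 else 420, NREM = 160,
             REM = 55)
  tr <- rbind(Wake = c(0, 1, 0),
              NREM = c(0.6, 0, 0.4),
              REM  = c(0.7, 0.3, 0))
  colnames(tr) <- STAGE_NAMES
  list(dwellMean = dwell, transition = tr)
}

#' Simulate a hypnogram
#'
#' Continuous-time semi-Markov simulation (exponential dwell with the
#' stage's mean, transitions from the embedded chain), discretized to epochs
#' by majority occupancy. Reproducible under `seed`.
#'
#' @param proc process spec as [hypnogramProcessDefaults()].
#' @param durationS total duration in seconds (at least one epoch).
#' @param epochLengthS epoch length in seconds (default 10).
#' @param seed RNG seed.
#' @return a [Hypnogram-class] with `floor(durationS / epochLengthS)` epochs.
#' @export
sampleHypnogram <- function(proc, durationS, epochLengthS = 10, seed = 0) {
  tr <- proc$transition
  .stopifnot1(is.matrix(tr) && all(dim(tr) == 3L) && all(tr >= 0) &&
                all(abs(rowSums(tr) - 1) < 1e-9) && all(diag(tr) == 0),
              "transition matrix must be 3x3 row-stochastic with zero ",
              "diagonal")
  .stopifnot1(all(proc$dwellMean > 0), "dwell times must be positive")
  nEpochs <- floor(durationS / epochLengthS)
  .stopifnot1(nEpochs >= 1, "duration shorter than one epoch")

  .withSeed(seed, {
    states <- integer(0); durs <- numeric(0)
    s <- 1L; total <- 0
    while (total < durationS) {
      d <- stats::rexp(1, rate = 1 / proc$dwellMean[s])
      states <- c(states, s); durs <- c(durs, d); total <- total + d
      s <- sample.int(3L, 1L, prob = tr[s, ])
    }
    # majority stage per epoch on a fine occupancy grid
    res <- epochLengthS / 100
    grid <- seq(res / 2, nEpochs * epochLengthS, by = res)
    stageAt <- states[findInterval(grid, cumsum(c(0, durs)),
                                   rightmost.closed = TRUE)]
    epochOf <- rep(seq_len(nEpochs), each = 100)
    maj <- vapply(split(stageAt, epochOf),
                  function(v) which.max(tabulate(v, 3L)), 1L)
    Hypnogram(unname(maj), epochLength = epochLengthS)
  })
}

#' Render a hypnogram as a synthetic EEG/EMG recording
#'
#' Each EEG channel is a sum over the six canonical bands of unit-RMS
#' band-limited noise (white noise filtered with the same FIR machinery the
#' feature extractor uses, so spectra leak across bins realistically),
#' weighted per epoch by the stage's band profile and amplitude scale, plus
#' a broadband noise floor and a 60 Hz line tone. The EMG channel is
#' broadband noise at the stage's EMG scale. All amplitudes are multiplied
#' by a per-subject gain, which exercises the per-recording feature
#' normalization.
#'
#' @param h a [Hypnogram-class].
#' @param sig stage signatures, see [stageSignatureDefaults()].
#' @param rate sampling rate in Hz (default 256; must exceed twice the
#'   highest band edge).
#' @param subjectGain positive amplitude gain.
#' @param lineNoiseAmp amplitude of the line-noise tone in microvolts.
#' @param lineFreq line frequency in Hz (default 60; tones above Nyquist
#'   are folded by sampling, as in a real digitizer).
#' @param seed RNG seed.
#' @param recordingId,subjectId,cycle recording metadata.
#' @return a [SleepRecording-class] with channels EEG1, EEG2, EMG.
#' @export
synthRecording <- function(h, sig = stageSignatureDefaults(), rate = 256,
                           subjectGain = 1, lineNoiseAmp = 5,
                           lineFreq = 60, seed = 0, recordingId = "synth",
                           subjectId = "subj", cycle = "unknown") {
  bands <- bandDefinitions()
  .stopifnot1(rate > 2 * max(bands$high),
              "rate must exceed twice the highest band edge (",
              2 * max(bands$high), " Hz)")
  .stopifnot1(subjectGain > 0, "subjectGain must be positive")
  nPer <- as.integer(round(h@epochLength * rate))
  n <- length(h@stages) * nPer
  st <- rep(h@stages, each = nPer)
  firs <- lapply(seq_len(nrow(bands)), function(b)
    designFIR(rate, bands$low[b], bands$high[b]))
  tt <- (seq_len(n) - 1) / rate

  .withSeed(seed, {
    eegChan <- function() {
      y <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        bn <- firFilter(stats::rnorm(n), firs[[b]])
        bn <- bn / sqrt(mean(bn^2))
        y <- y + sig$eegScale[st] * sqrt(sig$bandWeights[st, b]) * bn
      }
      y + sig$noise * stats::rnorm(n) +
        lineNoiseAmp * sin(2 * pi * lineFreq * tt + stats::runif(1, 0, 2 * pi))
    }
    sigs <- cbind(EEG1 = eegChan(), EEG2 = eegChan(),
                  EMG = sig$emgScale[st] * stats::rnorm(n) +
                    0.2 * lineNoiseAmp *
                    sin(2 * pi * lineFreq * tt + stats::runif(1, 0, 2 * pi)))
    SleepRecording(sigs * subjectGain, rate,
                   channelRoles = c("EEG1", "EEG2", "EMG"),
                   recordingId = recordingId, subjectId = subjectId,
                   cycle = cycle)
  })
}

#' Generate the synthetic benchmark dataset
#'
#' Writes ground-truth-labeled synthetic recordings as EDF files plus
#' hypnogram label files and a manifest. Default scale: 12 subjects x 2
#' recordings (one light-cycle, one dark-cycle) x 1 h at 256 Hz, each
#' subject with its own amplitude gain drawn uniformly from `gainRange`.
#' Per-recording seeds are derived from `seed`, so the dataset is fully
#' reproducible.
#'
#' @param dir output directory (created if needed).
#' @param nSubjects,recordingsPerSubject,durationS,rate dataset dimensions.
#' @param seed master seed.
#' @param separability stage-signature contrast, see
#'   [stageSignatureDefaults()].
#' @param gainRange range of per-subject amplitude gains.
#' @param lineNoiseAmp 60 Hz line tone amplitude in microvolts.
#' @param epochLengthS epoch length in seconds.
#' @return the manifest data.frame (columns `file`, `label_file`,
#'   `recording_id`, `subject_id`, `cycle`), also written to
#'   `dir/manifest.tsv`.
#' @export
makeBenchmark <- function(dir, nSubjects = 12, recordingsPerSubject = 2,
                          durationS = 3600, rate = 256, seed = 0,
                          separability = 1, gainRange = c(0.5, 2),
                          lineNoiseAmp = 5, epochLengthS = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- stageSignatureDefaults(separability)
  nRec <- nSubjects * recordingsPerSubject
  draws <- .withSeed(seed, list(
    gains = stats::runif(nSubjects, gainRange[1], gainRange[2]),
    seeds = matrix(sample.int(.Machine$integer.max %/% 4, 2L * nRec),
                   nRec, 2L)))
  manifest <- NULL
  r <- 0L
  for (i in seq_len(nSubjects)) {
    for (j in seq_len(recordingsPerSubject)) {
      r <- r + 1L
      cycle <- if (j %% 2L == 1L) "light" else "dark"
      subjectId <- sprintf("mouse%02d", i)
      recId <- sprintf("%s_rec%d_%s", subjectId, j, cycle)
      h <- sampleHypnogram(hypnogramProcessDefaults(cycle), durationS,
                           epochLengthS, seed = draws$seeds[r, 1])
      rec <- synthRecording(h, sig, rate = rate,
                            subjectGain = draws$gains[i],
                            lineNoiseAmp = lineNoiseAmp,
                            seed = draws$seeds[r, 2],
                            recordingId = recId, subjectId = subjectId,
                            cycle = cycle)
      edf <- file.path(dir, paste0(recId, ".edf"))
      txt <- file.path(dir, paste0(recId, ".txt"))
      writeEDF(rec, edf)
      writeHypnogram(h, txt)
      manifest <- rbind(manifest, data.frame(
        file = basename(edf), label_file = basename(txt),
        recording_id = recId, subject_id = subjectId, cycle = cycle,
        stringsAsFactors = FALSE))
    }
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
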