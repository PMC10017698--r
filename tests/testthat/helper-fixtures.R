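## Shared fixtures, built in code.

# three-channel recording whose EEG channels are pure tones and whose EMG is
# a tone of the given amplitude; whole seconds so EDF round trips exactly
toneRecording <- function(rate = 256, durationS = 20, eegFreq = 6,
                          eegAmp = 50, emgAmp = 20, emgFreq = 35,
                          recordingId = "tone", subjectId = "m1",
                          cycle = "light") {
  t <- seq(0, durationS - 1 / rate, by = 1 / rate)
  SleepRecording(
    cbind(EEG1 = eegAmp * sin(2 * pi * eegFreq * t),
          EEG2 = eegAmp * sin(2 * pi * (eegFreq + 2) * t),
          EMG = emgAmp * sin(2 * pi * emgFreq * t)),
    rate, c("EEG1", "EEG2", "EMG"),
    recordingId = recordingId, subjectId = subjectId, cycle = cycle)
}

# Gaussian feature clouds with class-specific means in the first three
# features; linearly separable when sep is large
stageClouds <- function(nPerClass = 60, p = 6, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(1:3, each = nPerClass)
  mu <- matrix(0, 3, p)
  mu[1, 1] <- sep; mu[2, 2] <- sep; mu[3, 3] <- sep
  x <- mu[y, ] + matrix(rnorm(length(y) * p), ncol = p)
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

# small labeled synthetic feature set through the real pipeline
smallPipelineSE <- function(durationS = 300, rate = 128, seed = 5,
                            subjectId = "m1", gain = 1) {
  h <- sampleHypnogram(hypnogramProcessDefaults("light"), durationS,
                       seed = seed)
  rec <- synthRecording(h, rate = rate, subjectGain = gain,
                        seed = seed + 1, subjectId = subjectId,
                        recordingId = paste0(subjectId, "_r1"))
  extractFeatures(rec, "two_eeg", stages = h)
}
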