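test_that("stage signatures encode the rodent discriminative structure", {
  sig <- stageSignatureDefaults()
  w <- sig$bandWeights
  expect_gt(w["NREM", "delta"], max(w["NREM", colnames(w) != "delta"]))
  expect_gt(w["REM", "theta"], max(w["REM", colnames(w) != "theta"]))
  expect_true(sig$emgScale["Wake"] > sig$emgScale["NREM"])
  expect_true(sig$emgScale["NREM"] > sig$emgScale["REM"])
  expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-12)
  # the difficulty knob shrinks contrast monotonically
  hard <- stageSignatureDefaults(0.2)
  expect_lt(hard$bandWeights["NREM", "delta"], w["NREM", "delta"])
  expect_lt(diff(range(hard$emgScale)), diff(range(sig$emgScale)))
})

test_that("hypnogram simulation is reproducible and rodent-like", {
  proc <- hypnogramProcessDefaults("light")
  h1 <- sampleHypnogram(proc, 3600, seed = 42)
  h2 <- sampleHypnogram(proc, 3600, seed = 42)
  expect_identical(stageCodes(h1), stageCodes(h2))
  expect_length(stageCodes(h1), 360)

  # dwell times far exceeding the duration -> a single-stage hypnogram
  still <- proc
  still$dwellMean <- c(Wake = 1e7, NREM = 1e7, REM = 1e7)
  expect_equal(unique(stageCodes(sampleHypnogram(still, 600, seed = 1))),
               1L)

  # over 20 seeds of 6 h: all stages present, REM rarer than NREM
  for (s in 1:20) {
    st <- stageCodes(sampleHypnogram(proc, 21600, seed = s))
    expect_setequal(unique(st), 1:3)
    expect_lt(sum(st == 3), sum(st == 2))
  }

  bad <- proc
  bad$transition[1, ] <- c(0, 0.5, 0.4)
  expect_error(sampleHypnogram(bad, 600), "row-stochastic")
})

test_that("dark-cycle recordings are wake-dominated relative to light", {
  wakeFrac <- function(cycle, s)
    mean(stageCodes(sampleHypnogram(hypnogramProcessDefaults(cycle),
                                    21600, seed = s)) == 1L)
  light <- mean(vapply(1:5, function(s) wakeFrac("light", s), 0))
  dark <- mean(vapply(1:5, function(s) wakeFrac("dark", s + 100), 0))
  expect_gt(dark, light + 0.15)
})

test_that("synthetic recordings carry the stage spectral signatures", {
  rate <- 128
  nrem <- synthRecording(Hypnogram(rep(2L, 12)), rate = rate, seed = 1)
  em <- sleepscoreR:::.epochMatrix(channelSignal(nrem, "EEG1"), 10 * rate)
  meanPow <- colMeans(t(apply(em, 2, bandPowers, rate = rate)))
  expect_gt(meanPow["delta"], max(meanPow[names(meanPow) != "delta"]))

  # REM epochs have the lowest EMG RMS of the three stages
  h <- Hypnogram(rep(1:3, each = 6))
  rec <- synthRecording(h, rate = rate, seed = 2)
  emg <- sleepscoreR:::.epochMatrix(channelSignal(rec, "EMG"), 10 * rate)
  rmsByStage <- tapply(sqrt(colMeans(emg^2)), stageCodes(h), mean)
  expect_lt(rmsByStage[["3"]], rmsByStage[["2"]])
  expect_lt(rmsByStage[["2"]], rmsByStage[["1"]])
})

test_that("the 60 Hz line tone is present and removed by preprocessing", {
  rate <- 256
  rec <- synthRecording(Hypnogram(rep(1L, 6)), rate = rate, seed = 3,
                        lineNoiseAmp = 20)
  x <- channelSignal(rec, "EEG1")
  sp <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * rate / length(x)
  pk <- function(v, lo, hi) max(v[f >= lo & f < hi])
  expect_gt(pk(sp, 59.9, 60.1), 10 * pk(sp, 50, 59))  # tone visible
  y <- channelSignal(preprocessRecording(rec), "EEG1")
  spf <- Mod(stats::fft(y))^2
  expect_lt(pk(spf, 59.9, 60.1), 1e-4 * pk(sp, 59.9, 60.1))
})

test_that("subject gain scales raw features, leaves normalized unchanged", {
  h <- sampleHypnogram(hypnogramProcessDefaults("light"), 120, seed = 5)
  r1 <- synthRecording(h, rate = 128, subjectGain = 1, seed = 6)
  r10 <- synthRecording(h, rate = 128, subjectGain = 10, seed = 6)
  expect_equal(signalMatrix(r10), 10 * signalMatrix(r1))
  a <- featureValues(extractFeatures(r1, "two_eeg"))
  b <- featureValues(extractFeatures(r10, "two_eeg"))
  raw <- "EEG2_time_broadband_rms_raw"
  expect_equal(b[, raw], 10 * a[, raw], tolerance = 1e-9)
  normCols <- grepl("_normmean$|_normmedian$", colnames(a))
  expect_equal(b[, normCols], a[, normCols], tolerance = 1e-9)
})

test_that("generator output is byte-identical under a fixed seed", {
  h <- sampleHypnogram(hypnogramProcessDefaults("light"), 60, seed = 7)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.edf"); p2 <- file.path(d, "b.edf")
  writeEDF(synthRecording(h, rate = 128, seed = 8), p1)
  writeEDF(synthRecording(h, rate = 128, seed = 8), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("benchmark generation writes the announced files and manifest", {
  d <- withr::local_tempdir()
  man <- makeBenchmark(d, nSubjects = 3, recordingsPerSubject = 2,
                       durationS = 60, rate = 128, seed = 1)
  expect_equal(nrow(man), 6)
  expect_length(unique(man$subject_id), 3)
  expect_true(all(file.exists(file.path(d, man$file))))
  expect_true(all(file.exists(file.path(d, man$label_file))))
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  expect_setequal(unique(man$cycle), c("light", "dark"))
  # labels align with the written recordings epoch-for-epoch
  h <- readHypnogram(file.path(d, man$label_file[1]))
  rec <- readEDF(file.path(d, man$file[1]))
  expect_equal(length(stageCodes(h)), nrow(segmentEpochs(rec)))
  # round trip through the reader preserves subject grouping metadata
  expect_equal(rec@subjectId, man$subject_id[1])
  expect_equal(rec@cycle, man$cycle[1])
})

test_that("shrinking stage separability degrades benchmark kappa", {
  kappaAt <- function(sep) {
    d <- withr::local_tempdir()
    man <- makeBenchmark(d, nSubjects = 4, recordingsPerSubject = 1,
                         durationS = 600, rate = 128, seed = 2,
                         separability = sep)
    se <- extractBatch(file.path(d, man$file),
                       labelFiles = file.path(d, man$label_file),
                       subjectIds = man$subject_id)
    subj <- SummarizedExperiment::colData(se)$subject_id
    test <- subj == "mouse04"
    m <- fitGBM(se[, !test], seed = 0, nRounds = 400,
                earlyStoppingRounds = 50, learningRate = 0.05)
    cohensKappa(confusionTable(featureStages(se[, test]),
                               predictStages(m, se[, test])))
  }
  ks <- vapply(c(1, 0.4, 0.1), kappaAt, 0)
  expect_gt(ks[1], ks[3])
  expect_gte(ks[2], ks[3])
})
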