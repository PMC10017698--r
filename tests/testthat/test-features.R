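test_that("schema counts match the canonical decomposition", {
  two <- featureSchema("two_eeg")
  one <- featureSchema("one_eeg")
  expect_equal(unname(schemaCounts(two)),
               c(291L, 138L, 15L, 45L, 246L))
  expect_equal(unname(schemaCounts(one)["total"]), 153L)
  # frequency-domain features per EEG channel
  expect_equal(sum(startsWith(schemaEntries(two), "EEG1_freq_")), 123L)
  expect_equal(sum(startsWith(schemaEntries(one), "EEG_freq_")), 123L)
  # EMG features are all time-domain
  emg <- grep("^EMG_", schemaEntries(two), value = TRUE)
  expect_length(emg, 15L)
  expect_true(all(grepl("_time_", emg)))
  # names are unique and encode the normalization
  expect_false(anyDuplicated(schemaEntries(two)) > 0)
  expect_equal(sum(grepl("_raw$", schemaEntries(two))), 97L)
  expect_equal(sum(grepl("_normmean$", schemaEntries(two))), 97L)
  expect_equal(sum(grepl("_normmedian$", schemaEntries(two))), 97L)
})

test_that("time statistics match closed forms and hand arithmetic", {
  expect_equal(unname(timeStats(rep(0, 100))), rep(0, 5))
  # [3, -4]
  ts <- timeStats(c(3, -4))
  expect_equal(unname(ts), c(3.5, 3.5, 4, 0.5, sqrt(12.5)))
  # sinusoid, amplitude 10, whole cycles: rms = A/sqrt(2), mean|x| = 2A/pi,
  # max = A (sampling grid hits the peak at 1 Hz / 1000 Hz)
  x <- 10 * sin(2 * pi * seq(0, 1 - 1e-3, by = 1e-3))
  ts <- timeStats(x)
  expect_equal(ts[["rms"]], 10 / sqrt(2), tolerance = 1e-6)
  expect_equal(ts[["mean_abs"]], 20 / pi, tolerance = 1e-3)
  expect_equal(ts[["max_abs"]], 10)
  expect_error(timeStats(numeric(0)), "empty")
})

test_that("1-40 Hz preprocessing attenuates line noise, passes 10 Hz", {
  rate <- 1000
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  mk <- function(x) SleepRecording(cbind(EEG1 = x, EMG = x), rate,
                                   c("EEG1", "EMG"))
  rms <- function(x) sqrt(mean(x^2))

  line <- 100 * sin(2 * pi * 60 * t)
  out <- channelSignal(preprocessRecording(mk(line)), "EEG1")
  expect_lt(rms(out), 2)                      # 60 Hz: < 2% of 100 uV

  tone <- 100 * sin(2 * pi * 10 * t)
  out <- channelSignal(preprocessRecording(mk(tone)), "EEG1")
  expect_lt(abs(rms(out) - rms(tone)) / rms(tone), 0.05)

  out <- channelSignal(preprocessRecording(mk(numeric(length(t)))), "EEG1")
  expect_equal(max(abs(out)), 0)

  expect_error(preprocessRecording(
    SleepRecording(cbind(EEG1 = rnorm(100), EMG = rnorm(100)), 80,
                   c("EEG1", "EMG"))), "sampling rate")
})

test_that("band powers land in the right band for pure tones", {
  rate <- 256; n <- 10 * rate
  mkTone <- function(f) sin(2 * pi * f * seq_len(n) / rate)
  p2 <- bandPowers(mkTone(2), rate)
  expect_gt(p2[["delta"]], 100 * max(p2[names(p2) != "delta"]))
  p6 <- bandPowers(mkTone(6), rate)
  expect_gt(p6[["theta"]], 100 * max(p6[names(p6) != "theta"]))
  expect_gt(p6[["theta"]] / p6[["delta"]], 100)
  expect_equal(unname(bandPowers(numeric(n), rate)), rep(0, 6))
  expect_error(bandPowers(mkTone(2), 60), "Nyquist")
})

test_that("band power scaling is comparable across sampling rates", {
  # same 10-s analog tone sampled at 1000 and 100 Hz: similar band power
  f <- 6
  p1k <- bandPowers(5 * sin(2 * pi * f * seq_len(10000) / 1000), 1000)
  p100 <- bandPowers(5 * sin(2 * pi * f * seq_len(1000) / 100), 100)
  expect_equal(p1k[["theta"]], p100[["theta"]], tolerance = 1e-6)
  expect_equal(p1k[["theta"]], 5^2 / 2, tolerance = 1e-6)  # A^2/2
  # band ranking identical for band-limited tones after resampling
  for (f in c(2, 6, 10, 20, 35)) {
    r1 <- bandPowers(sin(2 * pi * f * seq_len(10000) / 1000), 1000)
    r2 <- bandPowers(sin(2 * pi * f * seq_len(1000) / 100), 100)
    expect_identical(names(which.max(r1)), names(which.max(r2)))
  }
})

test_that("band ratios follow the printed definition with a guarded delta", {
  p <- c(delta = 1, theta = 1, alpha = 1, sigma = 1, beta = 1, lowgamma = 1)
  expect_equal(unname(bandRatios(p)), rep(1, 5))
  p2 <- c(delta = 4, theta = 8, alpha = 0, sigma = 0, beta = 0,
          lowgamma = 0)
  expect_equal(unname(bandRatios(p2)), c(2, 0, 0, 0, 0))
  pz <- p * 0
  expect_true(all(is.finite(bandRatios(pz))))
})

test_that("band-filtered statistics pass in-band and reject out-of-band", {
  rate <- 256; n <- 10 * rate
  x <- 10 * sin(2 * pi * 6 * seq_len(n) / rate)
  bands <- bandDefinitions()
  theta <- bandFilteredStats(x, rate, bands[bands$name == "theta", ])
  delta <- bandFilteredStats(x, rate, bands[bands$name == "delta", ])
  expect_equal(theta[["rms"]], 10 / sqrt(2), tolerance = 0.02)
  expect_lt(delta[["rms"]], 0.05 * 10 / sqrt(2))
  zero <- bandFilteredStats(numeric(n), rate, bands[1, ])
  expect_equal(unname(zero), rep(0, 5))
})

test_that("band-filtered powers sum to the broadband 1-40 Hz power", {
  set.seed(3)
  rate <- 256; n <- 10 * rate
  x <- rnorm(n)
  bands <- bandDefinitions()
  bandSum <- sum(vapply(seq_len(nrow(bands)), function(b)
    bandFilteredStats(x, rate, bands[b, ])[["rms"]]^2, 0))
  broadband <- sqrt(mean(firFilter(x, designFIR(rate, 1, 40))^2))^2
  expect_equal(bandSum, broadband, tolerance = 0.1)
})

test_that("per-recording normalization follows the mean/median rule", {
  nm <- normalizePerRecording(c(2, 4), c("r1", "r1"))
  expect_equal(nm$mean_normalized, c(2 / 3, 4 / 3))
  expect_equal(nm$median_normalized, c(2 / 3, 4 / 3))

  # identical epochs -> all ones
  m <- matrix(5, 4, 3)
  nm <- normalizePerRecording(m, rep("r1", 4))
  expect_equal(nm$mean_normalized, matrix(1, 4, 3))
  expect_equal(nm$median_normalized, matrix(1, 4, 3))

  # scale invariance and per-recording grouping
  set.seed(2)
  v <- abs(rnorm(6)) + 1
  ids <- rep(c("a", "b"), each = 3)
  n1 <- normalizePerRecording(v, ids)
  n2 <- normalizePerRecording(ifelse(ids == "a", 10 * v, v), ids)
  expect_equal(n1$mean_normalized, n2$mean_normalized)
  expect_equal(n1$median_normalized, n2$median_normalized)
})

test_that("extraction emits the canonical widths and EMG block", {
  rec <- toneRecording(rate = 128, durationS = 40)
  se2 <- extractFeatures(rec, "two_eeg")
  expect_equal(dim(se2), c(291L, 4L))
  expect_identical(rownames(se2), schemaEntries(featureSchema("two_eeg")))
  se1 <- extractFeatures(rec, "one_eeg", eegRole = "EEG2")
  expect_equal(nrow(se1), 153L)
  expect_error(extractFeatures(
    SleepRecording(signalMatrix(rec)[, c("EEG1", "EMG")], 128,
                   c("EEG1", "EMG")), "two_eeg"),
    "requires EEG1, EEG2 and EMG")
})

test_that("extraction is deterministic and gain-invariant where promised", {
  h <- sampleHypnogram(hypnogramProcessDefaults("light"), 120, seed = 3)
  rec <- synthRecording(h, rate = 128, seed = 4)
  a <- featureValues(extractFeatures(rec, "two_eeg"))
  b <- featureValues(extractFeatures(rec, "two_eeg"))
  expect_identical(a, b)                      # bit-identical

  rec10 <- rec
  rec10@signals <- rec10@signals * 10
  c10 <- featureValues(extractFeatures(rec10, "two_eeg"))
  normCols <- grepl("_normmean$|_normmedian$", colnames(a))
  expect_equal(c10[, normCols], a[, normCols], tolerance = 1e-12)
  # raw amplitude features scale by 10 (powers by 100)
  expect_equal(c10[, "EEG1_time_broadband_rms_raw"],
               10 * a[, "EEG1_time_broadband_rms_raw"])
  expect_equal(c10[, "EEG1_freq_delta_power_raw"],
               100 * a[, "EEG1_freq_delta_power_raw"])
  expect_true(all(is.finite(c10)))
})
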