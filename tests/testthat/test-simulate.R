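test_that("baseline noise is exactly RMS-normalized and deterministic", {
  spec <- simulationSpec(durationS = 30, fs = 500, seed = 4)
  nz1 <- generateBaselineNoise(spec)
  nz2 <- generateBaselineNoise(spec)
  expect_equal(length(samples(nz1)), 30 * 500)
  expect_lt(abs(rms(samples(nz1)) - 1), 1e-9)
  expect_identical(samples(nz1), samples(nz2))
  nz3 <- generateBaselineNoise(simulationSpec(durationS = 30, fs = 500, seed = 5))
  expect_false(identical(samples(nz1), samples(nz3)))
  spec2 <- simulationSpec(durationS = 30, fs = 500, seed = 4, noiseRms = 2.5)
  expect_lt(abs(rms(samples(generateBaselineNoise(spec2))) - 2.5), 1e-9)
})

test_that("noise PSD follows 1/f over the analysis band", {
  spec <- simulationSpec(durationS = 240, fs = 2000, seed = 7)
  nz <- generateBaselineNoise(spec)
  psd <- averagePsd(nz, segmentS = 10)
  sel <- psd$frequency >= 1 & psd$frequency <= 100
  fit <- lm(log10(power) ~ log10(frequency), psd[sel, ])
  expect_lt(abs(coef(fit)[2] + 1), 0.1)
})

test_that("epoch waveform has the requested peak, RMS and cycle count", {
  w <- makeEpochWaveform(3, 2, 2, 1, fs = 1000)
  expect_equal(length(w), 2000)
  expect_equal(max(abs(w)), 2, tolerance = 1e-6)
  expect_equal(rms(w), 2 / sqrt(2), tolerance = 1e-6)
  # 6 full cycles: 6 zero-crossing pairs of the sine
  expect_equal(sum(diff(sign(w)) > 0), 6)
  expect_true(all(makeEpochWaveform(3, 2, 0, 1, fs = 1000) == 0))
  expect_equal(rms(makeEpochWaveform(3, 2, 0.5, 1, fs = 1000)),
               0.5 / sqrt(2), tolerance = 1e-6)
  expect_error(makeEpochWaveform(-3, 2, 1, 1, fs = 1000), "freqHz")
  expect_error(makeEpochWaveform(3, 1e-9, 1, 1, fs = 100), "duration")
})

test_that("epoch embedding keeps exact truth bookkeeping and additivity", {
  spec <- smallSpec(seed = 2)
  nz <- generateBaselineNoise(spec)
  emb <- embedEpochs(nz, 3, 2, 2, 6, seed = 11)
  expect_equal(nrow(emb$truth), 6)
  expect_true(all(abs(emb$truth$offset_s - emb$truth$onset_s - 2) < 1e-9))
  expect_true(all(emb$truth$onset_s >= 0 & emb$truth$offset_s <= 120))
  diffSig <- samples(emb$trace) - samples(nz)
  tt <- (seq_along(diffSig) - 1) / samplingRate(nz)
  outside <- rep(TRUE, length(tt))
  for (i in seq_len(nrow(emb$truth)))
    outside[tt >= emb$truth$onset_s[i] - 1e-9 &
            tt < emb$truth$offset_s[i]] <- FALSE
  expect_true(all(diffSig[outside] == 0))
  expect_true(any(diffSig[!outside] != 0))
  # n = 0 leaves the trace untouched
  emb0 <- embedEpochs(nz, 3, 2, 2, 0, seed = 11)
  expect_identical(samples(emb0$trace), samples(nz))
  expect_equal(nrow(emb0$truth), 0)
})

test_that("non-overlapping placement yields pairwise disjoint epochs", {
  spec <- smallSpec(seed = 3)
  nz <- generateBaselineNoise(spec)
  emb <- embedEpochs(nz, 3, 2, 2, 10, seed = 5, overlapAllowed = FALSE)
  on <- sort(emb$truth$onset_s)
  expect_true(all(diff(on) >= 2 - 1e-9))
  expect_error(embedEpochs(nz, 3, 2, 2, 100, seed = 5, overlapAllowed = FALSE),
               "non-overlapping")
})

test_that("amplitude sweep shares noise and differs only inside epochs", {
  spec <- simulationSpec(durationS = 60, fs = 1000, nEpochs = 4, seed = 6,
                         amplitudeMultiples = c(2, 1))
  sw <- amplitudeSweep(spec)
  expect_named(sw, c("2", "1"))
  d <- samples(sw[["2"]]$trace) - samples(sw[["1"]]$trace)
  tt <- (seq_along(d) - 1) / 1000
  inside <- rep(FALSE, length(d))
  for (i in seq_len(nrow(sw[["2"]]$truth)))
    inside[tt >= sw[["2"]]$truth$onset_s[i] & tt < sw[["2"]]$truth$offset_s[i]] <- TRUE
  expect_true(all(d[!inside] == 0))
  expect_identical(sw[["2"]]$truth$onset_s, sw[["1"]]$truth$onset_s)
  # single multiple -> single trace; empty -> error
  spec1 <- simulationSpec(durationS = 60, fs = 1000, nEpochs = 4, seed = 6,
                          amplitudeMultiples = 2)
  expect_length(amplitudeSweep(spec1), 1)
})

test_that("empirical SNR matches the closed form", {
  expect_equal(closedFormSnrDb(2, 20, 2, 600), -8.75, tolerance = 1e-3)
  expect_equal(round(closedFormSnrDb(2, 20, 2, 600)), -9)
  expect_equal(closedFormSnrDb(0.5, 20, 2, 600), -20.79, tolerance = 0.01)
  expect_identical(closedFormSnrDb(0, 20, 2, 600), -Inf)
  spec <- simulationSpec(durationS = 300, fs = 1000, nEpochs = 10, seed = 8)
  for (a in c(2, 0.5)) {
    sim <- simulateRecording(spec, a)
    s <- snrDb(sim$trace, sim$noise)
    expect_false(s$undefined)
    expect_lt(abs(s$db - closedFormSnrDb(a, 10, 2, 300)), 0.3)
  }
  sim0 <- simulateRecording(spec, 1)
  z <- snrDb(sim0$noise, sim0$noise)
  expect_true(z$undefined)
  expect_identical(z$db, -Inf)
})

test_that("simulation spec validation rejects bad parameters", {
  expect_error(simulationSpec(durationS = -1), "positive")
  expect_error(simulationSpec(epochDurationS = 700), "exceed")
  expect_error(simulationSpec(amplitudeMultiples = c(1, -2)), "> 0")
  expect_error(simulationSpec(nEpochs = -1), ">= 0")
})
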