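test_that("frequency grid matches the closed form", {
  g <- buildFrequencyGrid()
  expect_length(g, 31)
  expect_equal(g[1], 0.3)
  expect_equal(g[31], 0.3 * 2^7.5, tolerance = 1e-9)
  expect_equal(buildFrequencyGrid(2, 4, 0.25),
               c(2, 2^1.25, 2^1.5, 2^1.75, 4), tolerance = 1e-9)
  expect_identical(buildFrequencyGrid(5, 5, 0.25), 5)
  expect_error(buildFrequencyGrid(-1, 4), "> 0")
  expect_error(buildFrequencyGrid(4, 2), ">=")
})

test_that("analysis resampling preserves in-band content and kills out-of-band", {
  fs <- 2000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tr3 <- SignalTrace(sin(2 * pi * 3 * t), fs)
  out <- resampleForAnalysis(tr3, 256)
  expect_equal(length(samples(out)), 60 * 256)
  expect_equal(samplingRate(out), 256)
  mid <- samples(out)[1000:14000]           # away from the circular edges
  expect_lt(abs(max(mid) - 1), 0.01)
  expect_lt(abs(rms(samples(out)) - 1 / sqrt(2)), 0.01)
  # content at 130 Hz (>= analysis Nyquist) attenuated by >= 40 dB
  trHi <- SignalTrace(sin(2 * pi * 130 * t), fs)
  outHi <- resampleForAnalysis(trHi, 256)
  expect_lt(20 * log10(rms(samples(outHi)) / rms(samples(trHi))), -40)
  expect_error(resampleForAnalysis(out, 512), "upsampling")
  expect_identical(resampleForAnalysis(out, 256), out)
})

test_that("Morlet transform localizes every default grid center", {
  fs <- 256
  grid <- buildFrequencyGrid()
  t <- seq(0, 90 - 1 / fs, by = 1 / fs)
  for (f0 in grid[seq(1, 31, by = 3)]) {
    tr <- SignalTrace(sin(2 * pi * f0 * t), fs)
    sc <- cwtMorlet(tr, grid)
    colMean <- colMeans(sc@magnitude)
    expect_equal(grid[which.max(colMean)], f0,
                 label = sprintf("argmax at %g Hz", f0))
    # unit sinusoid gives magnitude ~1 at its own center
    expect_lt(abs(mean(sc@magnitude[, which.max(colMean)]) - 1), 0.1)
  }
})

test_that("Morlet magnitude is linear in input scale and zero for silence", {
  fs <- 256
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tr <- SignalTrace(sin(2 * pi * 3 * t) + 0.3 * sin(2 * pi * 7 * t), fs)
  g <- buildFrequencyGrid(1, 16, 0.25)
  sc1 <- cwtMorlet(tr, g)
  sc2 <- cwtMorlet(SignalTrace(2 * samples(tr), fs), g)
  expect_equal(sc2@magnitude, 2 * sc1@magnitude, tolerance = 1e-9)
  sc0 <- cwtMorlet(SignalTrace(rep(0, length(t)), fs), g)
  expect_true(all(sc0@magnitude == 0))
  expect_error(cwtMorlet(tr, c(2, 200)), "Nyquist")
})

test_that("band averaging selects the right columns", {
  fs <- 256
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sc <- cwtMorlet(SignalTrace(sin(2 * pi * 3 * t), fs),
                  buildFrequencyGrid(1, 32, 0.25))
  single <- bandAverage(sc, 3.9, 4.1)   # contains only the 4 Hz center
  expect_equal(single@values, sc@magnitude[, which.min(abs(sc@freqs - 4))])
  lowBand <- bandAverage(sc, 2, 4)
  highBand <- bandAverage(sc, 8, 16)
  expect_gt(mean(lowBand@values), mean(highBand@values))
  expect_error(bandAverage(sc, 100, 200), "no grid center")
})

test_that("segment-wise normalization is scale-invariant with max 1", {
  set.seed(3)
  v <- abs(rnorm(3000)) + 0.1
  nb <- normalizeSegmentwise(v, fs = 100, segmentS = 10)
  expect_true(all(nb@values >= 0 & nb@values <= 1))
  for (s in seq(1, 3000, by = 1000))
    expect_equal(max(nb@values[s:(s + 999)]), 1)
  nb2 <- normalizeSegmentwise(v * 17, fs = 100, segmentS = 10)
  expect_equal(nb@values, nb2@values, tolerance = 1e-12)
  # idempotent
  nb3 <- normalizeSegmentwise(nb@values, fs = 100, segmentS = 10)
  expect_equal(nb3@values, nb@values, tolerance = 1e-12)
  # degenerate segment flagged and left at zero
  v2 <- c(rep(0, 1000), abs(rnorm(1000)) + 0.1)
  nb4 <- normalizeSegmentwise(v2, fs = 100, segmentS = 10)
  expect_identical(nb4@degenerateSegments, 1L)
  expect_true(all(nb4@values[1:1000] == 0))
})
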