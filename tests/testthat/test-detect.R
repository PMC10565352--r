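test_that("threshold fit recovers the parameters of a Gaussian baseline", {
  set.seed(42)
  for (r in 1:5) {
    v <- pmin(pmax(rnorm(20000, 0.3, 0.05), 0), 1)
    tm <- fitBaselineThreshold(v)
    expect_lt(abs(tm@mode - 0.3), 0.01)
    expect_lt(abs(tm@sigma - 0.05), 0.005)
    expect_equal(tm@threshold, min(tm@mode + 3 * tm@sigma, 1))
    # at k = 3 the baseline exceedance stays below 0.5%
    expect_lt(mean(v > tm@threshold), 0.005)
  }
})

test_that("threshold fit rejects degenerate input", {
  expect_error(fitBaselineThreshold(rep(0.5, 1000)), "degenerate")
  expect_error(fitBaselineThreshold(runif(50)), "fewer than 100")
  expect_error(fitBaselineThreshold(runif(1000) * 3), "normalize")
})

test_that("run segmentation applies merge-then-duration rules", {
  fs <- 100
  v <- rep(0.1, 3000)
  put <- function(v, from, to) { v[(from * fs + 1):(to * fs)] <- 0.9; v }
  # a single 0.4 s run is dropped
  es <- segmentEpochs(put(v, 10, 10.4), 0.5, fs = fs)
  expect_equal(nEpochs(es), 0)
  # runs at [10, 10.7] and [11, 11.6]: 0.3 s gap merges them
  es <- segmentEpochs(put(put(v, 10, 10.7), 11, 11.6), 0.5, fs = fs)
  expect_equal(nEpochs(es), 1)
  expect_equal(epochs(es)$start_s, 10)
  expect_equal(epochs(es)$end_s, 11.6)
  # a run of exactly 0.5 s is kept (inclusive boundary)
  es <- segmentEpochs(put(v, 10, 10.5), 0.5, fs = fs)
  expect_equal(nEpochs(es), 1)
  # two 0.3 s runs 0.2 s apart merge into one surviving 0.8 s epoch
  es <- segmentEpochs(put(put(v, 10, 10.3), 10.5, 10.8), 0.5, fs = fs)
  expect_equal(nEpochs(es), 1)
  expect_equal(epochs(es)$end_s - epochs(es)$start_s, 0.8)
  # a gap of exactly 0.5 s does NOT merge ("less than 0.5 s apart")
  es <- segmentEpochs(put(put(v, 10, 10.7), 11.2, 11.9), 0.5, fs = fs)
  expect_equal(nEpochs(es), 2)
  expect_error(segmentEpochs(v, 0, fs = fs), "threshold")
})

test_that("segmentation agrees exactly with the brute-force oracle", {
  set.seed(7)
  for (r in 1:200) {
    fs <- sample(c(10, 16, 50), 1)
    n <- sample(100:400, 1)
    # blocky random series so runs of many lengths occur
    v <- pmin(pmax(rep(runif(n %/% 5 + 1), each = 5)[1:n] +
                     rnorm(n, 0, 0.05), 0), 1)
    thr <- runif(1, 0.3, 0.9)
    es <- segmentEpochs(v, thr, fs = fs)
    orc <- oracleSegment(v, fs, thr)
    expect_equal(nEpochs(es), nrow(orc))
    if (nrow(orc)) {
      expect_equal(epochs(es)$start_s, orc$start_s, tolerance = 1e-9)
      expect_equal(epochs(es)$end_s, orc$end_s, tolerance = 1e-9)
      durs <- orc$end_s - orc$start_s
      expect_true(all(durs >= 0.5 - 1e-9))
      if (nrow(orc) > 1)
        expect_true(all(orc$start_s[-1] - orc$end_s[-nrow(orc)] >= 0.5 - 1e-9))
    }
  }
})

test_that("single-band detection recovers embedded epochs end to end", {
  sim <- simulateRecording(smallSpec(seed = 3), 2)
  es <- detectBand(sim$trace, band = c(2, 4))
  sc <- scoreDetection(es, sim$truth)
  expect_gte(sc$recovered, 5)  # 6 embedded
  expect_equal(sc$tp + sc$fn, sc$nTruth)
  # no gamma-band events for a 3 Hz epoch train beyond the noise FP level
  esG <- detectBand(sim$trace, band = c(30, 50))
  expect_lte(nEpochs(esG), 4)
})

test_that("pan-frequency scan returns one epoch set per center", {
  sim <- simulateRecording(smallSpec(seed = 5), 2)
  grid <- buildFrequencyGrid(1, 16, 0.25)
  sets <- panFrequencyScan(sim$trace, grid)
  expect_length(sets, length(grid))
  expect_named(sets, as.character(grid))
  counts <- vapply(sets, nEpochs, 1L)
  # recovered truth should concentrate in bands containing 3 Hz
  recs <- vapply(sets, function(es) scoreDetection(es, sim$truth)$recovered, 1L)
  near3 <- which.min(abs(grid - 3))
  expect_equal(recs[[near3]], max(recs))
  # zero trace -> every set empty
  z <- SignalTrace(rep(0, 256 * 40), 256)
  setsZ <- panFrequencyScan(z, buildFrequencyGrid(2, 8, 0.5))
  expect_true(all(vapply(setsZ, nEpochs, 1L) == 0))
})

test_that("class pooling dedups by interval union", {
  mk <- function(s, e, band) new("EpochSet",
    events = data.frame(start_s = s, end_s = e, peak_norm = rep(1, length(s))),
    traceDuration = 100, band = band, method = "wavelet", channel = "")
  # the same physical event seen in 3 adjacent bands counts once
  sets <- list(mk(10, 12, c(2, 4)), mk(10.1, 12, c(2.4, 4.8)),
               mk(10, 11.9, c(2.8, 5.7)))
  pooled <- poolClassEvents(sets, c(0.5, 8))
  expect_equal(nEpochs(pooled), 1)
  expect_equal(epochs(pooled)$start_s, 10)
  expect_equal(epochs(pooled)$end_s, 12)
  # disjoint events stay separate; out-of-class bands are excluded
  sets2 <- list(mk(c(10, 50), c(12, 51), c(2, 4)), mk(70, 72, c(30, 60)))
  pooled2 <- poolClassEvents(sets2, c(0.5, 8))
  expect_equal(nEpochs(pooled2), 2)
  expect_equal(nEpochs(poolClassEvents(list(), c(0.5, 8))), 0)
  # pooled events are re-checked against the minimum duration
  sets3 <- list(mk(10, 10.3, c(2, 4)))
  expect_equal(nEpochs(poolClassEvents(sets3, c(0.5, 8))), 0)
})
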