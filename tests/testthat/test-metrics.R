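mkSet <- function(s, e, dur = 600) new("EpochSet",
  events = data.frame(start_s = s, end_s = e, peak_norm = rep(1, length(s))),
  traceDuration = dur, band = c(2, 4), method = "wavelet", channel = "")

mkTruth <- function(on, d = 2)
  data.frame(onset_s = on, offset_s = on + d,
             freq_hz = rep(3, length(on)),
             amplitude_multiple = rep(1, length(on)))

test_that("detection scoring handles exact, empty and merged cases", {
  truth <- mkTruth(seq(10, 580, length.out = 20))
  exact <- mkSet(truth$onset_s, truth$offset_s)
  sc <- scoreDetection(exact, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$fp, 0)
  expect_equal(sc$recovered, 20)
  none <- scoreDetection(mkSet(numeric(0), numeric(0)), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fn, 20)
  # one detection spanning two truths: 1 TP + 1 FN, but both recovered
  t2 <- mkTruth(c(10, 12.5))
  sc2 <- scoreDetection(mkSet(9, 15), t2)
  expect_equal(sc2$tp, 1)
  expect_equal(sc2$fn, 1)
  expect_equal(sc2$recovered, 2)
})

test_that("scoring identities hold on randomized cases vs an overlap oracle", {
  set.seed(11)
  for (r in 1:100) {
    nT <- sample(0:10, 1)
    truth <- mkTruth(sort(runif(nT, 0, 580)))
    nD <- sample(0:12, 1)
    ds <- sort(runif(nD, 0, 595))
    # detections may overlap here, so score a plain data.frame
    detDf <- data.frame(start_s = ds, end_s = ds + runif(nD, 0.5, 4))
    sc <- scoreDetection(detDf, truth)
    expect_equal(sc$tp + sc$fn, nT)
    expect_gte(sc$tp, 0)
    expect_lte(sc$tp, min(nT, nD))
    covered <- vapply(seq_len(nT), function(i)
      any(detDf$start_s < truth$offset_s[i] &
          detDf$end_s > truth$onset_s[i]), TRUE)
    expect_equal(sc$recovered, sum(covered))
    expect_gte(sc$recovered, sc$tp)
  }
})

test_that("epoch statistics and LHR arithmetic", {
  es <- mkSet(seq(10, 580, length.out = 18), seq(10, 580, length.out = 18) + 2)
  st <- epochStats(es)
  expect_equal(st$rate, 0.03)
  expect_equal(st$meanDurationS, 2)
  empty <- epochStats(mkSet(numeric(0), numeric(0)))
  expect_equal(empty$rate, 0)
  expect_true(is.na(empty$meanDurationS))
  two <- epochStats(mkSet(c(1, 10), c(2.5, 12.5)))
  expect_equal(two$meanDurationS, 2)
  expect_equal(lhr(38, 2)$ratio, 19)
  expect_equal(lhr(5, 5)$ratio, 1)
  z <- lhr(10, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$ratio))
})

test_that("Cohen's d reproduces the worked effect sizes", {
  expect_equal(round(cohensD(6.7, 3.69), 2), 1.82)
  expect_lt(abs(cohensD(9.52, 4.61) - 2.06), 0.01)
  expect_equal(cohensD(0, 2), 0)
  expect_error(cohensD(1, 0), "> 0")
  # invariance to common rescaling, and agreement with hand pooling
  set.seed(2)
  a <- rnorm(8, 10, 2); b <- rnorm(8, 13, 3)
  d1 <- cohensDGroups(a, b)
  expect_equal(cohensDGroups(3 * a, 3 * b), d1, tolerance = 1e-12)
  sp <- sqrt((7 * var(a) + 7 * var(b)) / 14)
  expect_equal(d1, abs(mean(b) - mean(a)) / sp)
  dp <- cohensDGroups(a, b, "paired")
  expect_equal(dp, abs(mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2))
  expect_gte(d1, 0)
})

test_that("condition comparison statistics behave as designed", {
  a <- c(5, 7, 9, 6, 8, 7)
  cc0 <- compareConditions(a, a)
  expect_equal(cc0$percentChange, 0)
  expect_equal(cc0$cohensD, 0)
  # strictly monotone decrease: signed-rank statistic at its extreme (0)
  ccDec <- compareConditions(a, a - 1)
  expect_equal(unname(ccDec$wilcoxon$statistic), 0)
  expect_lt(ccDec$percentChange, 0)
  expect_error(compareConditions(a, a[-1]), "paired")
  expect_error(compareConditions(1, 2), "two pairs")
})

test_that("paired t test has power ~0.8+ for a 2-SD shift at n = 6", {
  set.seed(5)
  hits <- mean(replicate(400, {
    a <- rnorm(6)
    b <- a + 2 + rnorm(6) * 1e-8  # shift of 2 pooled SDs of the unit noise
    b <- b + rnorm(6)             # measurement noise in condition B
    compareConditions(a, b)$pairedT$p.value < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("time-course binning normalizes partial final bins", {
  tc <- timeCourse(c(100, 700, 1900, 3500), totalDurationS = 3600)
  expect_equal(nrow(tc), 6)
  expect_equal(tc$count, c(1, 1, 0, 1, 0, 1))
  expect_equal(tc$rate, tc$count / 600)
  # partial final bin
  tc2 <- timeCourse(c(50, 350), totalDurationS = 400, binS = 300)
  expect_equal(tc2$binEnd[2], 400)
  expect_equal(tc2$rate[2], 1 / 100)
  # a step change in rate shows up in the bins
  set.seed(8)
  ev <- c(runif(30, 0, 1800), runif(90, 1800, 3600))
  tc3 <- timeCourse(ev, 3600)
  expect_gt(mean(tc3$rate[4:6]), mean(tc3$rate[1:3]))
})

test_that("phase-amplitude coupling recovers a constructed coupling", {
  cp <- makeCoupledPair(durationS = 120, fs = 256, depth = 0.8,
                        phi0 = -pi / 3, seed = 21)
  pac <- phaseAmplitudeCoupling(cp$slow, cp$fast, nSurrogates = 200, seed = 5)
  expect_lt(pac$globalP, 0.05)
  expect_lt(abs(circDiff(pac$preferredPhase, cp$phi0)), pi / 8)
  expect_gte(pac$globalMi, 0)
  expect_gt(pac$fractionModulated, 0.5)
  # MI invariant to amplitude scaling of the fast trace
  pac2 <- phaseAmplitudeCoupling(cp$slow,
                                 SignalTrace(5 * samples(cp$fast), 256),
                                 nSurrogates = 50, seed = 5)
  expect_equal(pac2$globalMi, pac$globalMi, tolerance = 1e-9)
  expect_error(phaseAmplitudeCoupling(cp$slow,
                                      SignalTrace(rep(0, 120 * 256), 256)),
               "degenerate")
  expect_error(phaseAmplitudeCoupling(cp$slow, cp$fast, segmentS = 1),
               "3 cycles")
})

test_that("independent noise shows no coupling", {
  for (s in 1:5) {
    n1 <- generateBaselineNoise(simulationSpec(durationS = 60, fs = 256,
                                               seed = 100 + s))
    n2 <- generateBaselineNoise(simulationSpec(durationS = 60, fs = 256,
                                               seed = 200 + s))
    pac <- phaseAmplitudeCoupling(n1, n2, segmentS = 60, nSurrogates = 100,
                                  seed = s)
    expect_lt(pac$globalMi, 0.05)
  }
})
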