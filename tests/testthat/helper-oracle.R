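# Independent brute-force reference for suprathreshold run segmentation:
# walks the mask sample by sample, merges gaps shorter than mergeGap by
# repeatedly filling the shortest subthreshold gap, then drops short events.
oracleSegment <- function(vals, fs, threshold, minDur = 0.5, mergeGap = 0.5) {
  mask <- vals > threshold
  n <- length(mask)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  iv <- do.call(rbind, runs)
  # half-open seconds
  iv <- cbind((iv[, 1] - 1) / fs, iv[, 2] / fs)
  repeat {
    if (nrow(iv) < 2) break
    gaps <- iv[-1, 1] - iv[-nrow(iv), 2]
    g <- which.min(gaps)
    if (gaps[g] >= mergeGap - 1e-12) break
    iv[g, 2] <- iv[g + 1, 2]
    iv <- iv[-(g + 1), , drop = FALSE]
  }
  iv <- iv[iv[, 2] - iv[, 1] >= minDur - 1e-9, , drop = FALSE]
  data.frame(start_s = iv[, 1], end_s = iv[, 2])
}

# Small fast benchmark spec used across unit tests.
smallSpec <- function(seed = 1, nEpochs = 6L)
  simulationSpec(durationS = 120, fs = 1250, nEpochs = nEpochs, seed = seed)

# A coupled phase-amplitude pair driven by band-limited noise phase.
makeCoupledPair <- function(durationS = 120, fs = 256, depth = 0.8,
                            phi0 = -pi / 3, seed = 21) {
  nz <- generateBaselineNoise(simulationSpec(durationS = durationS, fs = fs,
                                             seed = seed))
  slow <- octaveBandpass(nz, centerHz = 1.5)
  phi <- Arg(analyticSignal(slow))
  t <- seq(0, durationS - 1 / fs, by = 1 / fs)
  fast <- (1 + depth * cos(phi - phi0)) * sin(2 * pi * 3 * t)
  list(slow = SignalTrace(slow, fs), fast = SignalTrace(fast, fs),
       phi0 = phi0)
}

circDiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}
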