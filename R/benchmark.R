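## Shared run/merge/duration machinery on a normalized series.
.detectFromSeries <- function(vals, fs, segmentS, nBins, k, smoothBins,
                              minDurationS, mergeGapS, band, method,
                              channel = "") {
  nb <- normalizeSegmentwise(vals, fs = fs, segmentS = segmentS)
  tm <- tryCatch(fitBaselineThreshold(nb, nBins = nBins, k = k,
                                      smoothBins = smoothBins),
                 error = function(e) NULL)
  if (is.null(tm)) {
    return(new("EpochSet",
               events = data.frame(start_s = numeric(0), end_s = numeric(0),
                                   peak_norm = numeric(0)),
               traceDuration = length(vals) / fs, band = band,
               method = method, channel = channel))
  }
  segmentEpochs(nb, tm, minDurationS = minDurationS, mergeGapS = mergeGapS,
                band = band, method = method, channel = channel)
}

#' Benchmark the detectors on the simulation sweep
#'
#' Runs the wavelet, amplitude-envelope and (optionally) STFT detectors over
#' simulated recordings at several epoch amplitudes and seeds, scoring each
#' against the embedded ground truth.  Within a seed the identical noise
#' realization and epoch placements are shared across amplitudes (paired
#' comparison); an amplitude of 0 denotes the pure-noise run used for
#' false-positive calibration.  The transforms of the noise and of the
#' unit-amplitude epoch component are computed once per seed and combined
#' linearly across amplitudes.
#'
#' @param spec a [SimulationSpec-class] (its seed slot is replaced by each
#'   element of \code{seeds}).
#' @param seeds integer vector of simulation seeds.
#' @param amplitudes epoch peak amplitudes (noise-RMS multiples) to test;
#'   0 rows (pure noise) are added when \code{includeNoiseOnly}.
#' @param band target band in Hz for the wavelet and STFT detectors.
#' @param methods subset of c("wavelet", "amplitude", "stft").
#' @param includeNoiseOnly add amplitude-0 rows?
#' @param spreadAt amplitudes at which the spectral spread of the detected
#'   epochs is measured (wavelet spread on a 0.5-16 Hz quarter-octave grid,
#'   STFT spread across its 8-Hz bins).
#' @param psdPeakAt amplitudes at which the averaged-PSD peak test is run
#'   at the epoch frequency.
#' @param analysisFs analysis rate, Hz.
#' @param kAmp amplitude-detector threshold multiplier.
#' @param segmentS,nBins,k,smoothBins,minDurationS,mergeGapS shared
#'   detection parameters.
#' @return data.frame with one row per (seed, method, amplitude):
#'   \code{method}, \code{amplitude}, \code{seed}, \code{nTruth}, \code{tp},
#'   \code{fp}, \code{fn}, \code{sensitivity}, \code{recovered},
#'   \code{fpPerMin}, \code{spreadHz}, \code{psdExcessDb},
#'   \code{psdPeakPresent}.
#' @export
runDetectorBenchmark <- function(spec, seeds = 1:10,
                                 amplitudes = spec@amplitudeMultiples,
                                 band = c(2, 4),
                                 methods = c("wavelet", "amplitude"),
                                 includeNoiseOnly = TRUE,
                                 spreadAt = numeric(0),
                                 psdPeakAt = numeric(0),
                                 analysisFs = 256, kAmp = 1.5, segmentS = 30,
                                 nBins = 100, k = 3, smoothBins = 5,
                                 minDurationS = 0.5, mergeGapS = 0.5) {
  methods <- match.arg(methods, c("wavelet", "amplitude", "stft"),
                       several.ok = TRUE)
  ampList <- sort(unique(c(amplitudes, if (includeNoiseOnly) 0)),
                  decreasing = TRUE)
  grid <- buildFrequencyGrid(band[1], band[2], 0.25)
  gridWide <- buildFrequencyGrid(0.5, 16, 0.25)
  rows <- list()
  for (sd in seeds) {
    sp <- spec
    sp@seed <- as.integer(sd)
    noise <- generateBaselineNoise(sp)
    placeSeed <- .subSeeds(sp@seed, 3L)[2]
    unit <- embedEpochs(noise, sp@epochFreqHz, sp@epochDurationS,
                        sp@noiseRms, sp@nEpochs, seed = placeSeed,
                        overlapAllowed = sp@overlapAllowed,
                        phaseMode = sp@epochPhaseMode)
    truth <- unit$truth
    comp <- unit$trace@samples - noise@samples
    x <- noise@samples
    fs <- sp@fs
    nOut <- round(sp@durationS * analysisFs)
    nr <- .fftResample(x, nOut)
    ur <- .fftResample(comp, nOut)
    Wx <- .morletCwt(nr, analysisFs, grid, 6)
    Wu <- .morletCwt(ur, analysisFs, grid, 6)
    if (length(spreadAt) && "wavelet" %in% methods) {
      WxW <- .morletCwt(nr, analysisFs, gridWide, 6)
      WuW <- .morletCwt(ur, analysisFs, gridWide, 6)
    }
    if ("stft" %in% methods) {
      nWin <- round(0.125 * analysisFs)
      sgX <- signal::specgram(nr, n = nWin, Fs = analysisFs,
                              overlap = nWin / 2)
      sgU <- signal::specgram(ur, n = nWin, Fs = analysisFs,
                              overlap = nWin / 2)
      frameFs <- analysisFs / (nWin / 2)
      stftFreqs <- as.numeric(sgX$f)
    }
    if ("amplitude" %in% methods) {
      w <- max(1L, round(0.5 * fs))
      envBase <- .slidingMean(x^2, w)
      envCross <- .slidingMean(x * comp, w)
      envUnit <- .slidingMean(comp^2, w)
      mX2 <- mean(x^2); mXU <- mean(x * comp); mU2 <- mean(comp^2)
    }
    for (a in ampList) {
      tr <- if (a == 0)
        data.frame(onset_s = numeric(0), offset_s = numeric(0))
      else truth
      addRow <- function(method, es, spread = NA_real_,
                         excess = NA_real_, present = NA) {
        sc <- scoreDetection(es, tr)
        rows[[length(rows) + 1]] <<- data.frame(
          method = method, amplitude = a, seed = sd,
          nTruth = sc$nTruth, tp = sc$tp, fp = sc$fp, fn = sc$fn,
          sensitivity = sc$sensitivity, recovered = sc$recovered,
          fpPerMin = sc$fp / (sp@durationS / 60), spreadHz = spread,
          psdExcessDb = excess, psdPeakPresent = present)
      }
      if ("wavelet" %in% methods) {
        mag <- if (a == 0) abs(Wx) else Mod(Wx + a * Wu)
        es <- .detectFromSeries(rowMeans(mag), analysisFs, segmentS, nBins,
                                k, smoothBins, minDurationS, mergeGapS,
                                band, "wavelet")
        spread <- NA_real_
        excess <- NA_real_
        present <- NA
        if (a %in% spreadAt) {
          magW <- if (a == 0) abs(WxW) else Mod(WxW + a * WuW)
          scW <- new("Scalogram", magnitude = magW, analysisFs = analysisFs,
                     freqs = gridWide, cycles = 6)
          spread <- scalogramSpread(scW, es)
        }
        if (a %in% psdPeakAt) {
          psd <- averagePsd(SignalTrace(x + a * comp, fs = fs), segmentS = 10)
          pk <- psdPeakPresent(psd, sp@epochFreqHz)
          excess <- pk$excessDb
          present <- pk$present
        }
        addRow("wavelet", es, spread, excess, present)
      }
      if ("amplitude" %in% methods) {
        env <- sqrt(pmax(envBase + 2 * a * envCross + a^2 * envUnit, 0))
        thr <- kAmp * sqrt(mX2 + 2 * a * mXU + a^2 * mU2)
        iv <- .maskToIntervals(env > thr, fs)
        iv <- .mergeIntervals(iv, mergeGapS)
        iv <- iv[(iv[, 2] - iv[, 1]) >= minDurationS - 1e-9, , drop = FALSE]
        es <- new("EpochSet",
                  events = data.frame(start_s = iv[, 1], end_s = iv[, 2],
                                      peak_norm = rep(NA_real_, nrow(iv))),
                  traceDuration = sp@durationS,
                  band = c(NA_real_, NA_real_), method = "amplitude",
                  channel = "")
        addRow("amplitude", es)
      }
      if ("stft" %in% methods) {
        S <- if (a == 0) Mod(sgX$S) else Mod(sgX$S + a * sgU$S)
        sg <- new("Spectrogram", magnitude = t(S), frameFs = frameFs,
                  freqs = stftFreqs, windowS = 0.125, overlap = 0.5)
        bt <- .stftBandSeries(sg, band)
        es <- .detectFromSeries(bt, frameFs, segmentS, nBins, k, smoothBins,
                                minDurationS, mergeGapS, band, "stft")
        spread <- NA_real_
        if (a %in% spreadAt && nEpochs(es) > 0) {
          tFrames <- (seq_len(nrow(sg@magnitude)) - 1) / frameFs
          inEv <- rep(FALSE, length(tFrames))
          for (r in seq_len(nEpochs(es)))
            inEv[tFrames >= es@events$start_s[r] &
                 tFrames < es@events$end_s[r]] <- TRUE
          if (any(inEv))
            spread <- spectralSpread(stftFreqs,
                                     colMeans(sg@magnitude[inEv, , drop = FALSE]))
        }
        addRow("stft", es, spread)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
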