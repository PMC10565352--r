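#' Segment-averaged power spectral density
#'
#' One-sided periodograms of consecutive non-overlapping rectangular-window
#' segments, averaged.  The density scaling is such that
#' \code{sum(power) * df} equals the mean signal power, so a unit-amplitude
#' sinusoid integrates to 1/2.
#'
#' @param trace a [SignalTrace-class].
#' @param segmentS segment length, seconds (default 10).
#' @return data.frame with columns \code{frequency} (Hz) and \code{power}
#'   (units^2/Hz), with attributes \code{nSegments} and \code{segmentS}.
#' @export
averagePsd <- function(trace, segmentS = 10) {
  stopifnot(is(trace, "SignalTrace"))
  fs <- trace@fs
  ns <- floor(segmentS * fs)
  x <- trace@samples
  nSeg <- floor(length(x) / ns)
  if (nSeg < 1) stop("trace shorter than one segment")
  half <- ns %/% 2
  acc <- numeric(half)
  for (i in seq_len(nSeg)) {
    X <- stats::fft(x[((i - 1) * ns + 1):(i * ns)])
    p <- (Mod(X[2:(half + 1)])^2) / (fs * ns)
    p[seq_len(half - 1)] <- 2 * p[seq_len(half - 1)]  # one-sided (not Nyquist)
    acc <- acc + p
  }
  out <- data.frame(frequency = (1:half) * fs / ns, power = acc / nSeg)
  attr(out, "nSegments") <- nSeg
  attr(out, "segmentS") <- segmentS
  out
}

#' Test for a distinct spectral peak
#'
#' Fits a straight line to log10(power) versus log10(frequency) over the fit
#' range, excluding a half-octave guard band around \code{f0}, and measures
#' the mean excess (in dB) of the observed power above the fitted background
#' inside the guard band.  A peak is declared when the excess reaches
#' \code{minExcessDb}.
#'
#' @param psd output of [averagePsd()].
#' @param f0 candidate peak frequency, Hz.
#' @param minExcessDb excess required to flag a peak (default 3 dB).
#' @param fitRange background fit range in Hz (default c(0.5, 20)).
#' @return list with \code{present} (logical) and \code{excessDb}.
#' @export
psdPeakPresent <- function(psd, f0, minExcessDb = 3, fitRange = c(0.5, 20)) {
  f <- psd$frequency
  p <- psd$power
  if (f0 <= min(f) || f0 >= max(f)) stop("f0 outside the PSD range")
  inRange <- f >= fitRange[1] & f <= fitRange[2]
  guard <- f >= f0 / sqrt(2) & f <= f0 * sqrt(2)
  bg <- inRange & !guard
  if (sum(bg) < 10) stop("insufficient background points for the fit")
  fit <- stats::lm(lp ~ lf, data.frame(lf = log10(f[bg]), lp = log10(p[bg])))
  sel <- inRange & guard
  pred <- stats::predict(fit, data.frame(lf = log10(f[sel])))
  excess <- mean(10 * (log10(p[sel]) - pred))
  list(present = excess >= minExcessDb, excessDb = excess)
}

#' Short-time Fourier transform spectrogram
#'
#' Magnitude spectrogram with a Hanning window; at the 256 Hz analysis rate
#' the default 0.125-s window is exactly 32 samples with a 16-sample hop and
#' 8 Hz frequency resolution.
#'
#' @param trace a [SignalTrace-class] at the analysis rate.
#' @param windowS window length, seconds (default 0.125).
#' @param overlap fractional overlap of consecutive windows (default 0.5).
#' @return a [Spectrogram-class].
#' @export
stftSpectrogram <- function(trace, windowS = 0.125, overlap = 0.5) {
  stopifnot(is(trace, "SignalTrace"))
  fs <- trace@fs
  nWin <- round(windowS * fs)
  if (nWin > length(trace@samples)) stop("window longer than the trace")
  hop <- round(nWin * (1 - overlap))
  sg <- signal::specgram(trace@samples, n = nWin, Fs = fs,
                         overlap = nWin - hop)
  new("Spectrogram", magnitude = t(Mod(sg$S)), frameFs = fs / hop,
      freqs = as.numeric(sg$f), windowS = windowS, overlap = overlap)
}

## Band series from a spectrogram: mean over bins whose half-width window
## intersects the band; falls back to the nearest bin.
.stftBandSeries <- function(sg, band) {
  df <- if (length(sg@freqs) > 1) sg@freqs[2] - sg@freqs[1] else Inf
  sel <- (sg@freqs + df / 2) >= band[1] & (sg@freqs - df / 2) <= band[2]
  if (!any(sel)) sel <- which.min(abs(sg@freqs - mean(band)))
  rowMeans(sg@magnitude[, sel, drop = FALSE])
}

#' Epoch detection from an STFT spectrogram
#'
#' The spectrogram's band-average series is passed through the same
#' normalization, histogram-threshold and run-segmentation machinery as the
#' wavelet path, so the method comparison isolates the time-frequency
#' representation.  The spectral spread of the detections is the full width
#' at half prominence of the spectrogram's time-averaged spectrum across the
#' detected epochs.
#'
#' @param trace a [SignalTrace-class] (resampled internally if needed).
#' @param band c(lo, hi) target band, Hz.
#' @param analysisFs analysis rate, Hz.
#' @param windowS,overlap spectrogram parameters.
#' @param segmentS,nBins,k,smoothBins,minDurationS,mergeGapS detection
#'   parameters shared with the wavelet path.
#' @return list with \code{epochs} (an [EpochSet-class], method "stft") and
#'   \code{spreadHz}.
#' @export
stftDetect <- function(trace, band = c(2, 4), analysisFs = 256,
                       windowS = 0.125, overlap = 0.5, segmentS = 30,
                       nBins = 100, k = 3, smoothBins = 5,
                       minDurationS = 0.5, mergeGapS = 0.5) {
  stopifnot(is(trace, "SignalTrace"))
  tr <- if (trace@fs > analysisFs) resampleForAnalysis(trace, analysisFs) else trace
  sg <- stftSpectrogram(tr, windowS, overlap)
  bt <- .stftBandSeries(sg, band)
  nb <- normalizeSegmentwise(bt, fs = sg@frameFs, segmentS = segmentS)
  tm <- fitBaselineThreshold(nb, nBins = nBins, k = k, smoothBins = smoothBins)
  es <- segmentEpochs(nb, tm, minDurationS = minDurationS,
                      mergeGapS = mergeGapS, band = band, method = "stft",
                      channel = trace@label)
  spread <- NA_real_
  if (nEpochs(es) > 0) {
    tFrames <- (seq_len(nrow(sg@magnitude)) - 1) / sg@frameFs
    inEv <- rep(FALSE, length(tFrames))
    for (r in seq_len(nEpochs(es)))
      inEv[tFrames >= es@events$start_s[r] & tFrames < es@events$end_s[r]] <- TRUE
    if (any(inEv))
      spread <- spectralSpread(sg@freqs,
                               colMeans(sg@magnitude[inEv, , drop = FALSE]))
  }
  list(epochs = es, spreadHz = spread)
}

#' Spectral spread of detected epochs in a scalogram
#'
#' Full width at half prominence of the scalogram's time-averaged magnitude
#' spectrum across the events of an [EpochSet-class].
#'
#' @param scalogram a [Scalogram-class].
#' @param epochSet an [EpochSet-class].
#' @return spread in Hz (NA when no event samples exist).
#' @export
scalogramSpread <- function(scalogram, epochSet) {
  stopifnot(is(scalogram, "Scalogram"), is(epochSet, "EpochSet"))
  tt <- (seq_len(nrow(scalogram@magnitude)) - 1) / scalogram@analysisFs
  inEv <- rep(FALSE, length(tt))
  ev <- epochSet@events
  for (r in seq_len(nrow(ev)))
    inEv[tt >= ev$start_s[r] & tt < ev$end_s[r]] <- TRUE
  if (!any(inEv)) return(NA_real_)
  spectralSpread(scalogram@freqs,
                 colMeans(scalogram@magnitude[inEv, , drop = FALSE]))
}

#' Sliding-RMS amplitude envelope
#'
#' Root-mean-square of the signal over a centered sliding window; edge
#' windows are truncated so the output length equals the input length.  For
#' a sustained sinusoid of peak a the steady-state envelope is a/sqrt(2).
#'
#' @param trace a [SignalTrace-class] or numeric vector.
#' @param smoothS window length, seconds (default 0.5).
#' @param fs sampling rate (required for numeric input).
#' @return numeric envelope, nonnegative, same length as the input.
#' @export
amplitudeEnvelope <- function(trace, smoothS = 0.5, fs = NULL) {
  if (is(trace, "SignalTrace")) {
    x <- trace@samples; fs <- trace@fs
  } else {
    if (is.null(fs)) stop("fs is required for a numeric input")
    x <- as.numeric(trace)
  }
  if (smoothS <= 0) stop("smoothS must be > 0")
  w <- max(1L, round(smoothS * fs))
  sqrt(pmax(.slidingMean(x^2, w), 0))
}

#' Amplitude-envelope epoch detection
#'
#' The whole-trace RMS represents baseline noise; events are sustained
#' excursions of the smoothed envelope above \code{kAmp} times that RMS,
#' subject to the same minimum-duration and merge rules as the other
#' detectors.  During an epoch of peak amplitude a (in noise-RMS units) the
#' expected window RMS is sqrt(1 + a^2/2), so the default multiplier 1.5
#' separates epochs of 1.5x RMS amplitude (window RMS 1.46) from 1.0x
#' (window RMS 1.22), reproducing the published detection limit of this
#' method.
#'
#' @param trace a [SignalTrace-class].
#' @param kAmp threshold multiplier on the whole-trace RMS (default 1.5).
#' @param smoothS envelope smoothing window, seconds.
#' @param minDurationS,mergeGapS segmentation rules.
#' @return an [EpochSet-class] with method tag "amplitude".
#' @export
amplitudeDetect <- function(trace, kAmp = 1.5, smoothS = 0.5,
                            minDurationS = 0.5, mergeGapS = 0.5) {
  stopifnot(is(trace, "SignalTrace"))
  x <- trace@samples
  if (max(x) - min(x) < 1e-12) stop("degenerate trace")
  env <- amplitudeEnvelope(trace, smoothS)
  thr <- kAmp * rms(x)
  iv <- .maskToIntervals(env > thr, trace@fs)
  iv <- .mergeIntervals(iv, mergeGapS)
  keep <- (iv[, 2] - iv[, 1]) >= minDurationS - 1e-9
  iv <- iv[keep, , drop = FALSE]
  peak <- vapply(seq_len(nrow(iv)), function(r) {
    i0 <- max(1L, floor(iv[r, 1] * trace@fs) + 1L)
    i1 <- min(length(env), ceiling(iv[r, 2] * trace@fs))
    max(env[i0:i1]) / thr
  }, 1)
  new("EpochSet",
      events = data.frame(start_s = iv[, 1], end_s = iv[, 2],
                          peak_norm = peak),
      traceDuration = duration(trace), band = c(NA_real_, NA_real_),
      method = "amplitude", channel = trace@label)
}
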