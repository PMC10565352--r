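#' Octave-spaced frequency grid
#'
#' Center frequencies \code{fMin * 2^(k * stepOctaves)} for k = 0, 1, ...
#' while the center does not exceed \code{fMax}.  The default grid spans
#' 0.3 to 64 Hz at 0.25-octave spacing (31 centers, the last at
#' 0.3 * 2^7.5 = 54.3 Hz).
#'
#' @param fMin lowest center, Hz.
#' @param fMax upper bound for centers, Hz.
#' @param stepOctaves spacing in octaves.
#' @return numeric vector of center frequencies.
#' @examples
#' length(buildFrequencyGrid())        # 31
#' buildFrequencyGrid(2, 4, 0.25)      # 2.000 2.378 2.828 3.364 4.000
#' @export
buildFrequencyGrid <- function(fMin = 0.3, fMax = 64, stepOctaves = 0.25) {
  if (fMin <= 0 || stepOctaves <= 0) stop("fMin and stepOctaves must be > 0")
  if (fMax < fMin) stop("fMax must be >= fMin")
  kMax <- floor(log2(fMax / fMin) / stepOctaves + 1e-9)
  fMin * 2^(stepOctaves * (0:kMax))
}

#' Resample a trace to the analysis rate
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency and inverted at the new length.  In-band sinusoid amplitudes
#' are preserved essentially exactly and content above the new Nyquist is
#' removed entirely.
#'
#' @param trace a [SignalTrace-class].
#' @param targetFs analysis sampling rate, Hz (default 256).
#' @return a [SignalTrace-class] of \code{round(duration * targetFs)}
#'   samples.
#' @export
resampleForAnalysis <- function(trace, targetFs = 256) {
  stopifnot(is(trace, "SignalTrace"))
  if (targetFs > trace@fs)
    stop("targetFs exceeds the input sampling rate; upsampling not supported")
  if (targetFs == trace@fs) return(trace)
  nOut <- round(duration(trace) * targetFs)
  SignalTrace(.fftResample(trace@samples, nOut), fs = targetFs,
              t0 = trace@t0, label = trace@label)
}

## Complex Morlet transform via frequency-domain convolution with reflection
## padding of one wavelet support (6 sigma_t of the lowest frequency).
## The wavelet's frequency response is a Gaussian centered on f with
## sigma_f = f / cycles, scaled by 2 so an in-band unit-amplitude sinusoid
## has magnitude 1 at its center frequency.
.morletCwt <- function(x, fs, freqs, cycles = 6) {
  n <- length(x)
  sigTmax <- cycles / (2 * pi * min(freqs))
  pad <- min(n, ceiling(6 * sigTmax * fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  np <- length(xp)
  X <- stats::fft(xp)
  fgrid <- (0:(np - 1)) * fs / np
  pos <- fgrid > 0 & fgrid <= fs / 2
  out <- matrix(0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigF <- f / cycles
    H <- numeric(np)
    H[pos] <- 2 * exp(-(fgrid[pos] - f)^2 / (2 * sigF^2))
    y <- stats::fft(X * H, inverse = TRUE) / np
    out[, j] <- y[(pad + 1):(pad + n)]
  }
  out
}

#' Continuous Morlet wavelet transform
#'
#' Magnitude scalogram of the trace on an octave-spaced frequency grid.
#' The transform is computed over the full trace by frequency-domain
#' convolution with reflection padding of one wavelet support at each end
#' (at 0.3 Hz the wavelet support exceeds a 30-s segment, so per-segment
#' transforms would be edge-dominated).  The magnitude is linear in input
#' amplitude and scaled so a unit sinusoid at a grid center has magnitude
#' about 1 in that column.
#'
#' @param trace a [SignalTrace-class] at the analysis rate.
#' @param freqs frequency grid centers, Hz (see [buildFrequencyGrid()]).
#' @param cycles Morlet cycle parameter (time-frequency trade-off;
#'   default 6).
#' @return a [Scalogram-class].
#' @export
cwtMorlet <- function(trace, freqs = buildFrequencyGrid(), cycles = 6) {
  stopifnot(is(trace, "SignalTrace"))
  freqs <- sort(as.numeric(freqs))
  if (max(freqs) >= trace@fs / 2)
    stop("grid frequency at or above Nyquist")
  W <- .morletCwt(trace@samples, trace@fs, freqs, cycles)
  new("Scalogram", magnitude = abs(W), analysisFs = trace@fs, freqs = freqs,
      cycles = cycles)
}

#' Average scalogram magnitude over a frequency band
#'
#' Per-time mean of the scalogram magnitude across all grid centers c with
#' fLo <= c <= fHi.
#'
#' @param scalogram a [Scalogram-class].
#' @param fLo,fHi band bounds in Hz.
#' @return a [BandAverageTrace-class] (not yet normalized).
#' @export
bandAverage <- function(scalogram, fLo, fHi) {
  stopifnot(is(scalogram, "Scalogram"))
  sel <- scalogram@freqs >= fLo - 1e-9 & scalogram@freqs <= fHi + 1e-9
  if (!any(sel)) stop("band [", fLo, ", ", fHi, "] contains no grid center")
  vals <- rowMeans(scalogram@magnitude[, sel, drop = FALSE])
  new("BandAverageTrace", values = vals, fs = scalogram@analysisFs,
      band = c(fLo, fHi), normalized = FALSE)
}

#' Segment-wise normalization of a band-average trace
#'
#' Each consecutive segment of \code{segmentS} seconds is divided by its own
#' maximum, mirroring per-segment normalized scalogram displays; values end
#' up in [0, 1] with every non-degenerate segment reaching exactly 1.
#' All-zero segments are flagged and left at 0.
#'
#' @param x a [BandAverageTrace-class] or numeric vector.
#' @param fs sampling rate (required when \code{x} is numeric).
#' @param segmentS normalization segment length, seconds (default 30).
#' @return a normalized [BandAverageTrace-class].
#' @export
normalizeSegmentwise <- function(x, fs = NULL, segmentS = 30) {
  if (segmentS <= 0) stop("segmentS must be > 0")
  if (is(x, "BandAverageTrace")) {
    vals <- x@values; fs <- x@fs; band <- x@band
  } else {
    if (is.null(fs)) stop("fs is required for a numeric input")
    vals <- as.numeric(x); band <- c(NA_real_, NA_real_)
  }
  ns <- round(segmentS * fs)
  n <- length(vals)
  degenerate <- integer(0)
  segIdx <- 0L
  for (s in seq(1, n, by = ns)) {
    segIdx <- segIdx + 1L
    e <- min(s + ns - 1, n)
    m <- max(vals[s:e])
    if (m > 0) vals[s:e] <- vals[s:e] / m
    else degenerate <- c(degenerate, segIdx)
  }
  new("BandAverageTrace", values = vals, fs = fs, band = band,
      segmentS = segmentS, normalized = TRUE,
      degenerateSegments = degenerate)
}
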