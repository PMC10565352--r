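## Zero-phase Butterworth band-pass (order 2, applied forward and backward).
.bandpass <- function(x, fs, band) {
  wn <- band / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1)) stop("band outside (0, Nyquist)")
  bf <- signal::butter(2, wn, type = "pass")
  signal::filtfilt(bf, x)
}

## Tort-style modulation index from phase and amplitude series: mean
## amplitude per phase bin, normalized to a distribution P; MI is the
## KL divergence of P from uniform, scaled by log(nBins) into [0, 1].
.modulationIndex <- function(phase, amp, nBins = 18) {
  bins <- pmin(floor((phase + pi) / (2 * pi) * nBins) + 1L, nBins)
  meanAmp <- vapply(seq_len(nBins), function(b) {
    s <- amp[bins == b]
    if (length(s)) mean(s) else 0
  }, 1)
  if (sum(meanAmp) <= 0) return(0)
  p <- meanAmp / sum(meanAmp)
  p <- p[p > 0]
  (log(nBins) + sum(p * log(p))) / log(nBins)
}

#' Cross-frequency phase-amplitude coupling
#'
#' Quantifies the dependence of a fast rhythm's amplitude on a slow rhythm's
#' phase (e.g. coupling of the 3 Hz cortical amplitude to the 1.5 Hz
#' thalamic phase).  Both traces are band-passed to octave-wide bands
#' centered on \code{phaseCenter} and \code{ampCenter}; the instantaneous
#' phase of the slow signal and amplitude envelope of the fast signal are
#' taken from their analytic signals.  Per analysis segment, the modulation
#' index is the Kullback-Leibler-based index over an 18-bin phase-binned
#' amplitude distribution; its significance is assessed against surrogates
#' built by circularly time-shifting the amplitude series by random offsets.
#' The preferred phase is the amplitude-weighted circular mean phase.
#'
#' @param slowTrace,fastTrace time-aligned [SignalTrace-class] objects with
#'   equal sampling rates (phase provider and amplitude provider).
#' @param phaseCenter,ampCenter band centers, Hz (defaults 1.5 and 3).
#' @param widthOctaves band width, octaves (default 1).
#' @param segmentS analysis segment length, seconds (default 30).
#' @param nSurrogates surrogate count per segment (default 200).
#' @param nBins phase bins (default 18).
#' @param alpha per-segment significance level (default 0.05).
#' @param seed integer seed for the surrogate shifts.
#' @return list with \code{segments} (data.frame: segment, mi, p,
#'   preferredPhase, modulated), \code{globalMi}, \code{globalP},
#'   \code{preferredPhase} (circular mean over modulated segments, or all
#'   segments when none is modulated), \code{fractionModulated},
#'   \code{phaseBand}, \code{ampBand}.
#' @export
phaseAmplitudeCoupling <- function(slowTrace, fastTrace, phaseCenter = 1.5,
                                   ampCenter = 3, widthOctaves = 1,
                                   segmentS = 30, nSurrogates = 200,
                                   nBins = 18, alpha = 0.05, seed = 1) {
  stopifnot(is(slowTrace, "SignalTrace"), is(fastTrace, "SignalTrace"))
  if (slowTrace@fs != fastTrace@fs)
    stop("traces must share a sampling rate")
  if (length(slowTrace@samples) != length(fastTrace@samples))
    stop("traces must be time-aligned with equal length")
  fs <- slowTrace@fs
  if (max(abs(fastTrace@samples)) == 0) stop("degenerate amplitude (zero fast trace)")
  phaseBand <- phaseCenter * 2^(c(-1, 1) * widthOctaves / 2)
  ampBand <- ampCenter * 2^(c(-1, 1) * widthOctaves / 2)
  slow <- .bandpass(slowTrace@samples, fs, phaseBand)
  fast <- .bandpass(fastTrace@samples, fs, ampBand)
  phase <- Arg(.analyticSignal(slow))
  amp <- Mod(.analyticSignal(fast))
  n <- length(phase)
  segLen <- round(segmentS * fs)
  if (segLen < 3 * fs / phaseCenter)
    stop("segment shorter than 3 cycles of the phase frequency")
  starts <- seq(1, n - segLen + 1, by = segLen)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  minShift <- max(round(fs / phaseCenter), 1L)   # at least one slow cycle
  segRes <- lapply(seq_along(starts), function(si) {
    idx <- starts[si]:(starts[si] + segLen - 1)
    ph <- phase[idx]; am <- amp[idx]
    mi <- .modulationIndex(ph, am, nBins)
    shifts <- sample(seq(minShift, segLen - minShift), nSurrogates,
                     replace = TRUE)
    surr <- vapply(shifts, function(s)
      .modulationIndex(ph, c(am[(s + 1):segLen], am[seq_len(s)]), nBins), 1)
    p <- (1 + sum(surr >= mi)) / (1 + nSurrogates)
    pref <- Arg(sum(am * exp(1i * ph)))
    data.frame(segment = si, mi = mi, p = p, preferredPhase = pref,
               modulated = p < alpha)
  })
  segs <- do.call(rbind, segRes)
  ## whole-recording index and surrogate p
  miAll <- .modulationIndex(phase, amp, nBins)
  shifts <- sample(seq(minShift, n - minShift), nSurrogates, replace = TRUE)
  surrAll <- vapply(shifts, function(s)
    .modulationIndex(phase, c(amp[(s + 1):n], amp[seq_len(s)]), nBins), 1)
  pAll <- (1 + sum(surrAll >= miAll)) / (1 + nSurrogates)
  use <- if (any(segs$modulated)) segs$modulated else rep(TRUE, nrow(segs))
  prefGlobal <- Arg(sum(exp(1i * segs$preferredPhase[use])))
  list(segments = segs, globalMi = miAll, globalP = pAll,
       preferredPhase = prefGlobal,
       fractionModulated = mean(segs$modulated),
       phaseBand = phaseBand, ampBand = ampBand)
}

#' Octave-band zero-phase filtering
#'
#' Band-pass a signal to an octave-wide (by default) band centered on
#' \code{centerHz}, using a zero-phase order-2 Butterworth filter.
#'
#' @param x a [SignalTrace-class] or numeric vector.
#' @param centerHz band center, Hz.
#' @param widthOctaves band width in octaves (default 1).
#' @param fs sampling rate (required for numeric input).
#' @return filtered numeric vector.
#' @export
octaveBandpass <- function(x, centerHz, widthOctaves = 1, fs = NULL) {
  if (is(x, "SignalTrace")) { fs <- x@fs; x <- x@samples }
  if (is.null(fs)) stop("fs is required for a numeric input")
  .bandpass(as.numeric(x), fs, centerHz * 2^(c(-1, 1) * widthOctaves / 2))
}

#' Analytic signal
#'
#' Complex analytic signal via the frequency-domain Hilbert construction;
#' its argument is the instantaneous phase and its modulus the amplitude
#' envelope.
#'
#' @param x a [SignalTrace-class] or numeric vector.
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  if (is(x, "SignalTrace")) x <- x@samples
  .analyticSignal(as.numeric(x))
}
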