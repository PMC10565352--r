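#' Define a simulation benchmark specification
#'
#' Parameterizes the synthetic benchmark: 1/f baseline noise of unit RMS in
#' which brief sinusoidal oscillation epochs are embedded at random onsets.
#' The defaults are the published benchmark conditions: 600 s at 12.5 kHz,
#' spectral exponent 1, twenty 2-s epochs of a 3 Hz sinusoid, and an
#' amplitude sweep over peak amplitudes 2x, 1x, 0.5x, 0.25x, 0.125x,
#' 0.0625x and 0.03125x the noise RMS.
#'
#' @param durationS total duration in seconds.
#' @param fs sampling rate in Hz.
#' @param noiseExponent spectral exponent alpha of the 1/f^alpha noise PSD.
#' @param noiseRms RMS the baseline noise is normalized to (exactly).
#' @param epochFreqHz epoch oscillation frequency, Hz.
#' @param epochDurationS epoch duration, seconds.
#' @param nEpochs number of embedded epochs.
#' @param amplitudeMultiples epoch peak amplitudes as multiples of noise RMS.
#' @param seed integer seed controlling all randomness.
#' @param overlapAllowed may epochs overlap one another?
#' @param epochPhaseMode \code{"random-per-epoch"} (default) or
#'   \code{"fixed-zero"}.
#' @param firTaps 1/f FIR filter length in taps; \code{NA} (default) selects
#'   \code{2^ceiling(log2(5 * fs)) + 1}, about five seconds of samples, so
#'   the filter can realize the 1/f magnitude down to a fraction of a hertz.
#' @return a [SimulationSpec-class] object.
#' @examples
#' spec <- simulationSpec(durationS = 60, fs = 1000, nEpochs = 5, seed = 1)
#' @export
simulationSpec <- function(durationS = 600, fs = 12500, noiseExponent = 1,
                           noiseRms = 1, epochFreqHz = 3, epochDurationS = 2,
                           nEpochs = 20,
                           amplitudeMultiples = c(2, 1, 0.5, 0.25, 0.125,
                                                  0.0625, 0.03125),
                           seed = 1, overlapAllowed = TRUE,
                           epochPhaseMode = c("random-per-epoch", "fixed-zero"),
                           firTaps = NA) {
  epochPhaseMode <- match.arg(epochPhaseMode)
  if (is.na(firTaps)) firTaps <- 2L^as.integer(ceiling(log2(5 * fs))) + 1L
  new("SimulationSpec", durationS = durationS, fs = fs,
      noiseExponent = noiseExponent, noiseRms = noiseRms,
      epochFreqHz = epochFreqHz, epochDurationS = epochDurationS,
      nEpochs = as.integer(nEpochs), amplitudeMultiples = amplitudeMultiples,
      seed = as.integer(seed), overlapAllowed = overlapAllowed,
      epochPhaseMode = epochPhaseMode, firTaps = as.integer(firTaps))
}

## Linear-phase FIR whose magnitude response follows f^(-alpha/2), i.e. a
## 1/f^alpha power spectrum, flat below fKnee to avoid DC blow-up.
.pinkFir <- function(fs, nTaps, alpha = 1, fKnee = 0.1) {
  nyq <- fs / 2
  if (fKnee >= nyq) stop("sampling rate too low for the 1/f passband")
  fgrid <- c(0, fKnee, exp(seq(log(fKnee * 1.01), log(nyq * 0.9999),
                               length.out = 60)), nyq)
  amp <- pmax(fgrid, fKnee)^(-alpha / 2)
  amp <- amp / amp[2]
  fgrid[length(fgrid)] <- nyq
  gridN <- 2L^as.integer(ceiling(log2(nTaps))) * 2L
  signal::fir2(nTaps - 1, fgrid / nyq, amp, grid_n = gridN)
}

#' Generate 1/f baseline noise
#'
#' Gaussian white noise is passed through a linear-phase FIR filter whose
#' magnitude response is proportional to f^(-alpha/2), producing a power
#' spectral density proportional to 1/f^alpha (flat below 0.1 Hz).  The
#' filter start-up transient (one filter length) is trimmed, and the trace
#' is then rescaled so its RMS equals \code{noiseRms} exactly.  The output
#' is a deterministic function of the spec's seed.
#'
#' @param spec a [SimulationSpec-class].
#' @return a [SignalTrace-class] of length \code{durationS * fs}.
#' @examples
#' nz <- generateBaselineNoise(simulationSpec(durationS = 30, fs = 500, seed = 1))
#' rms(samples(nz))  # exactly 1
#' @export
generateBaselineNoise <- function(spec) {
  validObject(spec)
  n <- round(spec@durationS * spec@fs)
  nTaps <- spec@firTaps
  if (n < nTaps)
    warning("trace shorter than the 1/f filter; spectral shaping is degraded")
  seedNoise <- .subSeeds(spec@seed, 3L)[1]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seedNoise)
  w <- stats::rnorm(n + nTaps)
  h <- .pinkFir(spec@fs, nTaps, spec@noiseExponent)
  x <- signal::fftfilt(h, w)[(nTaps + 1):(nTaps + n)]
  x <- x * (spec@noiseRms / rms(x))
  SignalTrace(x, fs = spec@fs, label = "sim-noise")
}

#' Construct a sinusoidal epoch waveform
#'
#' A plain sinusoid (no taper) whose peak amplitude is
#' \code{amplitudeMultiple * noiseRms}; its RMS is peak/sqrt(2).
#'
#' @param freqHz oscillation frequency, Hz.
#' @param durationS epoch duration, seconds.
#' @param amplitudeMultiple peak amplitude as a multiple of \code{noiseRms}.
#' @param noiseRms reference noise RMS.
#' @param fs sampling rate, Hz.
#' @param phase initial phase in radians.
#' @return numeric vector of \code{round(durationS * fs)} samples.
#' @examples
#' w <- makeEpochWaveform(3, 2, 2, 1, fs = 250)
#' max(abs(w))       # peak 2
#' rms(w)            # 2/sqrt(2)
#' @export
makeEpochWaveform <- function(freqHz, durationS, amplitudeMultiple,
                              noiseRms = 1, fs, phase = 0) {
  if (freqHz <= 0) stop("freqHz must be > 0")
  if (amplitudeMultiple < 0) stop("amplitudeMultiple must be >= 0")
  nSamp <- round(durationS * fs)
  if (nSamp < 1) stop("duration shorter than one sample")
  t <- (seq_len(nSamp) - 1) / fs
  amplitudeMultiple * noiseRms * sin(2 * pi * freqHz * t + phase)
}

#' Embed sinusoidal epochs into a noise trace
#'
#' Adds \code{nEpochs} copies of a sinusoidal epoch at onsets drawn
#' uniformly over [0, duration - epochDuration], aligned to the sample
#' grid.  Superposition is strictly additive: outside the union of the
#' returned truth intervals the output equals the input noise exactly.
#'
#' @param noise a [SignalTrace-class] baseline.
#' @param freqHz epoch frequency, Hz.
#' @param durationS epoch duration, seconds.
#' @param peakAmplitude epoch peak amplitude (same units as the noise).
#' @param nEpochs number of epochs to place.
#' @param seed integer seed for placements and phases.
#' @param overlapAllowed if \code{FALSE}, placements are redrawn until all
#'   epochs are pairwise disjoint (error after 10000 attempts).
#' @param phaseMode \code{"random-per-epoch"} or \code{"fixed-zero"}.
#' @return list with elements \code{trace} (a [SignalTrace-class]) and
#'   \code{truth}, a data.frame with columns \code{onset_s}, \code{offset_s},
#'   \code{freq_hz}, \code{amplitude_multiple} (here the peak amplitude in
#'   noise-RMS units, assuming unit-RMS noise input).
#' @export
embedEpochs <- function(noise, freqHz, durationS, peakAmplitude, nEpochs,
                        seed = 1, overlapAllowed = TRUE,
                        phaseMode = c("random-per-epoch", "fixed-zero")) {
  phaseMode <- match.arg(phaseMode)
  stopifnot(is(noise, "SignalTrace"))
  fs <- noise@fs
  n <- length(noise@samples)
  lenEp <- round(durationS * fs)
  if (lenEp > n) stop("epoch waveform does not fit within the trace")
  x <- noise@samples
  nEpochs <- as.integer(nEpochs)
  if (nEpochs == 0L) {
    return(list(trace = noise,
                truth = data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                   freq_hz = numeric(0),
                                   amplitude_multiple = numeric(0))))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  maxStart <- n - lenEp            # 0-based start sample
  draw <- function() floor(stats::runif(nEpochs, 0, maxStart + 1))
  starts <- draw()
  if (!overlapAllowed) {
    ok <- function(s) {
      s <- sort(s); all(diff(s) >= lenEp)
    }
    tries <- 0L
    while (!ok(starts)) {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("could not place ", nEpochs, " non-overlapping epochs")
      starts <- draw()
    }
  }
  starts <- sort(starts)
  phases <- if (phaseMode == "random-per-epoch")
    stats::runif(nEpochs, 0, 2 * pi) else rep(0, nEpochs)
  for (i in seq_len(nEpochs)) {
    idx <- (starts[i] + 1):(starts[i] + lenEp)
    x[idx] <- x[idx] + makeEpochWaveform(freqHz, durationS, peakAmplitude,
                                         1, fs, phases[i])
  }
  truth <- data.frame(onset_s = starts / fs,
                      offset_s = starts / fs + lenEp / fs,
                      freq_hz = freqHz,
                      amplitude_multiple = peakAmplitude)
  list(trace = SignalTrace(x, fs = fs, label = noise@label), truth = truth)
}

#' Simulate one benchmark recording
#'
#' Convenience wrapper: generates the 1/f baseline and embeds the epochs at
#' one amplitude multiple.  All randomness derives from \code{spec@seed}
#' through independent sub-streams for noise, placements, and phases.
#'
#' @param spec a [SimulationSpec-class].
#' @param amplitudeMultiple epoch peak amplitude in noise-RMS multiples
#'   (default: the first entry of the spec's sweep).
#' @return list with \code{trace}, \code{noise} (both [SignalTrace-class]),
#'   and \code{truth} (data.frame).
#' @export
simulateRecording <- function(spec, amplitudeMultiple = spec@amplitudeMultiples[1]) {
  noise <- generateBaselineNoise(spec)
  placeSeed <- .subSeeds(spec@seed, 3L)[2]
  emb <- embedEpochs(noise, spec@epochFreqHz, spec@epochDurationS,
                     amplitudeMultiple * spec@noiseRms, spec@nEpochs,
                     seed = placeSeed, overlapAllowed = spec@overlapAllowed,
                     phaseMode = spec@epochPhaseMode)
  list(trace = emb$trace, noise = noise, truth = emb$truth)
}

#' Amplitude sweep of the benchmark
#'
#' One simulated recording per amplitude multiple.  In shared-noise mode
#' (default) the identical noise realization, epoch placements and phases
#' are reused across amplitudes, so any two traces differ only inside the
#' truth intervals; this enables paired detector comparisons.
#'
#' @param spec a [SimulationSpec-class].
#' @param sharedNoise reuse one noise realization and one set of placements
#'   across all amplitudes?
#' @return named list (names = amplitude multiples); each element is a list
#'   with \code{trace}, \code{truth}, and \code{noise}.
#' @export
amplitudeSweep <- function(spec, sharedNoise = TRUE) {
  if (!length(spec@amplitudeMultiples)) stop("empty amplitude list")
  seeds <- .subSeeds(spec@seed, 3L)
  noise <- generateBaselineNoise(spec)
  out <- vector("list", length(spec@amplitudeMultiples))
  names(out) <- as.character(spec@amplitudeMultiples)
  if (sharedNoise) {
    unit <- embedEpochs(noise, spec@epochFreqHz, spec@epochDurationS,
                        spec@noiseRms, spec@nEpochs, seed = seeds[2],
                        overlapAllowed = spec@overlapAllowed,
                        phaseMode = spec@epochPhaseMode)
    comp <- unit$trace@samples - noise@samples
    for (i in seq_along(spec@amplitudeMultiples)) {
      a <- spec@amplitudeMultiples[i]
      truth <- unit$truth
      truth$amplitude_multiple <- a
      out[[i]] <- list(trace = SignalTrace(noise@samples + a * comp,
                                           fs = spec@fs, label = noise@label),
                       truth = truth, noise = noise)
    }
  } else {
    for (i in seq_along(spec@amplitudeMultiples)) {
      a <- spec@amplitudeMultiples[i]
      emb <- embedEpochs(noise, spec@epochFreqHz, spec@epochDurationS,
                         a * spec@noiseRms, spec@nEpochs,
                         seed = seeds[2] + i,
                         overlapAllowed = spec@overlapAllowed,
                         phaseMode = spec@epochPhaseMode)
      out[[i]] <- list(trace = emb$trace, truth = emb$truth, noise = noise)
    }
  }
  out
}

#' Whole-trace signal-to-noise ratio in dB
#'
#' The epoch component is \code{trace - noise}; the SNR is
#' \code{10 log10(mean(epoch^2) / mean(noise^2))} over the full trace.
#'
#' @param trace the composite [SignalTrace-class].
#' @param noise the baseline-noise [SignalTrace-class].
#' @return list with \code{db} (numeric; \code{-Inf} when the epoch
#'   component is identically zero) and \code{undefined} flag.
#' @examples
#' # closed form: a 2x-RMS epoch amplitude over the default protocol is
#' # 10*log10(2 * 40/600) = -8.75 dB, printed as -9 dB
#' closedFormSnrDb(2, 20, 2, 600)
#' @export
snrDb <- function(trace, noise) {
  stopifnot(is(trace, "SignalTrace"), is(noise, "SignalTrace"))
  if (length(trace@samples) != length(noise@samples))
    stop("trace and noise must have the same length")
  e <- trace@samples - noise@samples
  pe <- mean(e^2)
  pn <- mean(noise@samples^2)
  if (pn <= 0) stop("noise power must be positive")
  if (pe == 0) return(list(db = -Inf, undefined = TRUE))
  list(db = 10 * log10(pe / pn), undefined = FALSE)
}

#' @rdname snrDb
#' @param amplitudeMultiple epoch peak amplitude in noise-RMS multiples.
#' @param nEpochs number of epochs.
#' @param epochDurationS epoch duration, seconds.
#' @param totalDurationS trace duration, seconds.
#' @export
closedFormSnrDb <- function(amplitudeMultiple, nEpochs, epochDurationS,
                            totalDurationS) {
  if (amplitudeMultiple == 0 || nEpochs == 0) return(-Inf)
  10 * log10((amplitudeMultiple^2 / 2) * (nEpochs * epochDurationS) /
             totalDurationS)
}
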