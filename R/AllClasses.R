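#' @import methods
NULL

#' SignalTrace: a uniformly sampled signal
#'
#' The universal container for recorded or simulated voltage traces: an
#' ordered vector of real amplitudes together with its sampling rate, start
#' time and a free-text channel label.
#'
#' @slot samples numeric vector of amplitudes (microvolts or arbitrary units).
#' @slot fs sampling rate in Hz.
#' @slot t0 start time of the first sample, in seconds.
#' @slot label channel identifier.
#' @export
setClass("SignalTrace",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 label = "character"),
  prototype(t0 = 0, label = ""))

setValidity("SignalTrace", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "'samples' must contain at least one sample")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' SimulationSpec: parameters of the synthetic oscillation-epoch benchmark
#'
#' Describes a simulated recording: 1/f ("pink") baseline noise of a given
#' RMS with a controlled number of sinusoidal oscillation epochs embedded at
#' random onsets.  The defaults reproduce the published benchmark: a 10-min
#' recording at 12.5 kHz, unit-RMS 1/f noise, and twenty 2-s epochs of a
#' 3 Hz sinusoid swept over peak amplitudes of 2x down to 1/32x the noise
#' RMS.
#'
#' @slot durationS total duration, seconds.
#' @slot fs sampling rate, Hz.
#' @slot noiseExponent spectral exponent alpha; noise PSD is proportional to
#'   1/f^alpha.
#' @slot noiseRms RMS of the baseline noise after exact normalization.
#' @slot epochFreqHz oscillation frequency of the embedded epochs, Hz.
#' @slot epochDurationS duration of each epoch, seconds.
#' @slot nEpochs number of embedded epochs.
#' @slot amplitudeMultiples epoch peak amplitudes, as multiples of the noise
#'   RMS, used by [amplitudeSweep()].
#' @slot seed integer seed; all randomness (noise, placements, phases) is a
#'   deterministic function of it.
#' @slot overlapAllowed may epochs overlap each other?
#' @slot epochPhaseMode \code{"random-per-epoch"} or \code{"fixed-zero"}.
#' @slot firTaps length of the 1/f-shaping FIR filter; \code{NA} selects
#'   about five seconds of samples (see [generateBaselineNoise()]).
#' @export
setClass("SimulationSpec",
  representation(durationS = "numeric", fs = "numeric",
                 noiseExponent = "numeric", noiseRms = "numeric",
                 epochFreqHz = "numeric", epochDurationS = "numeric",
                 nEpochs = "integer", amplitudeMultiples = "numeric",
                 seed = "integer", overlapAllowed = "logical",
                 epochPhaseMode = "character", firTaps = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  if (object@durationS <= 0 || object@fs <= 0)
    msg <- c(msg, "duration and sampling rate must be positive")
  n <- object@durationS * object@fs
  if (abs(n - round(n)) > 1e-8)
    msg <- c(msg, "durationS * fs must be an integer number of samples")
  if (object@nEpochs < 0L)
    msg <- c(msg, "nEpochs must be >= 0")
  if (object@epochDurationS > object@durationS)
    msg <- c(msg, "epochDurationS must not exceed durationS")
  if (any(object@amplitudeMultiples <= 0))
    msg <- c(msg, "all amplitude multiples must be > 0")
  if (!object@epochPhaseMode %in% c("random-per-epoch", "fixed-zero"))
    msg <- c(msg, "epochPhaseMode must be 'random-per-epoch' or 'fixed-zero'")
  if (object@noiseRms <= 0)
    msg <- c(msg, "noiseRms must be > 0")
  if (length(msg)) msg else TRUE
})

#' Scalogram: Morlet wavelet magnitude over time and frequency
#'
#' @slot magnitude nonnegative matrix, time (rows) by frequency (columns).
#' @slot analysisFs sampling rate of the rows, Hz.
#' @slot freqs center frequencies of the columns, Hz.
#' @slot cycles the Morlet cycle parameter (number of cycles under the
#'   Gaussian envelope).
#' @export
setClass("Scalogram",
  representation(magnitude = "matrix", analysisFs = "numeric",
                 freqs = "numeric", cycles = "numeric"))

setValidity("Scalogram", function(object) {
  msg <- character(0)
  if (ncol(object@magnitude) != length(object@freqs))
    msg <- c(msg, "one magnitude column per frequency is required")
  if (any(object@magnitude < 0))
    msg <- c(msg, "magnitudes must be nonnegative")
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' BandAverageTrace: per-band average wavelet magnitude
#'
#' The time course of Morlet magnitude averaged across the grid centers of
#' one frequency band, optionally normalized per analysis segment so that
#' every segment's maximum is 1.
#'
#' @slot values the band-average series; in [0, 1] once normalized.
#' @slot fs sampling rate of the series, Hz.
#' @slot band the (low, high) frequency bounds of the band, Hz.
#' @slot segmentS normalization segment length in seconds (NA before
#'   normalization).
#' @slot normalized has segment-wise normalization been applied?
#' @slot degenerateSegments indices of all-zero (flagged) segments.
#' @export
setClass("BandAverageTrace",
  representation(values = "numeric", fs = "numeric", band = "numeric",
                 segmentS = "numeric", normalized = "logical",
                 degenerateSegments = "integer"),
  prototype(segmentS = NA_real_, normalized = FALSE,
            degenerateSegments = integer(0)))

#' ThresholdModel: fitted baseline model of a normalized band trace
#'
#' The histogram of a normalized band-average trace shows a Gaussian-like
#' baseline bulk skewed to the right by sparse epochs.  The model records
#' the bulk's mode, its spread, and the detection threshold
#' \code{mode + k * sigma} (clipped to 1).
#'
#' @slot mode center of the baseline bulk (midpoint of the histogram
#'   peak's half-maximum interval; the mode of a Gaussian bulk).
#' @slot sigma spread of the baseline bulk (FWHM / 2.3548).
#' @slot k threshold multiplier.
#' @slot threshold detection threshold, \code{min(mode + k * sigma, 1)}.
#' @slot nBins number of histogram bins used.
#' @export
setClass("ThresholdModel",
  representation(mode = "numeric", sigma = "numeric", k = "numeric",
                 threshold = "numeric", nBins = "integer"))

setValidity("ThresholdModel", function(object) {
  msg <- character(0)
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@mode < 0 || object@mode >= object@threshold)
    msg <- c(msg, "mode must satisfy 0 <= mode < threshold")
  if (length(msg)) msg else TRUE
})

#' EpochSet: detected oscillation epochs from one trace and band
#'
#' Events are half-open intervals [start_s, end_s) sorted by onset and
#' non-overlapping within the band after merging.
#'
#' @slot events data.frame with columns \code{start_s}, \code{end_s},
#'   \code{peak_norm} (peak normalized magnitude inside the event).
#' @slot traceDuration duration of the analyzed trace, seconds.
#' @slot band (low, high) frequency bounds in Hz (NA for broadband methods).
#' @slot method detection method tag: \code{"wavelet"}, \code{"stft"} or
#'   \code{"amplitude"}.
#' @slot channel channel label.
#' @export
setClass("EpochSet",
  representation(events = "data.frame", traceDuration = "numeric",
                 band = "numeric", method = "character",
                 channel = "character"),
  prototype(band = c(NA_real_, NA_real_), method = "wavelet", channel = ""))

setValidity("EpochSet", function(object) {
  ev <- object@events
  msg <- character(0)
  if (!all(c("start_s", "end_s", "peak_norm") %in% names(ev)))
    msg <- c(msg, "events must have columns start_s, end_s, peak_norm")
  if (nrow(ev)) {
    if (any(ev$start_s < 0)) msg <- c(msg, "event starts must be >= 0")
    if (any(ev$end_s <= ev$start_s)) msg <- c(msg, "events must have positive duration")
    if (is.unsorted(ev$start_s)) msg <- c(msg, "events must be sorted by onset")
    if (nrow(ev) > 1 && any(ev$start_s[-1] < ev$end_s[-nrow(ev)]))
      msg <- c(msg, "events must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Spectrogram: short-time Fourier transform magnitude
#'
#' @slot magnitude nonnegative matrix, time frame (rows) by frequency bin
#'   (columns).
#' @slot frameFs frame rate (rows per second), Hz.
#' @slot freqs frequency bin centers, Hz.
#' @slot windowS analysis window length, seconds.
#' @slot overlap fractional overlap of consecutive windows.
#' @export
setClass("Spectrogram",
  representation(magnitude = "matrix", frameFs = "numeric", freqs = "numeric",
                 windowS = "numeric", overlap = "numeric"))

#' GridRecording: a multichannel recording sharing one clock
#'
#' Channels of a multielectrode-array recording (e.g. an 8 x 8 grid where
#' label "11" is row 1, column 1), all sharing a sampling rate and length.
#'
#' @slot channels named list of [SignalTrace-class] objects.
#' @slot fs shared sampling rate, Hz.
#' @slot units amplitude units (e.g. "uV").
#' @slot metadata free-form list (subject, condition, bath glucose, ...).
#' @export
setClass("GridRecording",
  representation(channels = "list", fs = "numeric", units = "character",
                 metadata = "list"),
  prototype(units = "uV", metadata = list()))

setValidity("GridRecording", function(object) {
  msg <- character(0)
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  if (!all(vapply(object@channels, is, TRUE, "SignalTrace")))
    msg <- c(msg, "all channels must be SignalTrace objects")
  else {
    fss <- vapply(object@channels, function(tr) tr@fs, 1)
    lens <- vapply(object@channels, function(tr) length(tr@samples), 1L)
    if (length(unique(fss)) > 1L || any(fss != object@fs))
      msg <- c(msg, "all channels must share the recording sampling rate")
    if (length(unique(lens)) > 1L)
      msg <- c(msg, "all channels must have the same length")
  }
  labs <- names(object@channels)
  if (is.null(labs) || anyDuplicated(labs))
    msg <- c(msg, "channel labels must be unique and non-empty")
  if (length(msg)) msg else TRUE
})
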