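#' Construct a SignalTrace
#'
#' @param samples numeric vector of amplitudes.
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @param label channel label.
#' @return a [SignalTrace-class] object.
#' @examples
#' tr <- SignalTrace(sin(2 * pi * 3 * seq(0, 2, by = 1/250)), fs = 250)
#' duration(tr)
#' @export
SignalTrace <- function(samples, fs, t0 = 0, label = "") {
  new("SignalTrace", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0), label = as.character(label))
}

#' @rdname accessors
#' @export
setMethod("samples", "SignalTrace", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "SignalTrace", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("startTime", "SignalTrace", function(x) x@t0)

#' @rdname accessors
#' @export
setMethod("traceLabel", "SignalTrace", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("duration", "SignalTrace", function(x) length(x@samples) / x@fs)

setMethod("show", "SignalTrace", function(object) {
  cat(sprintf("SignalTrace%s: %d samples at %g Hz (%.3f s), rms %.4g\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(object@samples), object@fs, duration(object),
              rms(object@samples)))
})

#' @rdname accessors
#' @export
setMethod("duration", "EpochSet", function(x) x@traceDuration)

#' @rdname accessors
#' @export
setMethod("epochs", "EpochSet", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) nrow(x@events))

#' @rdname accessors
#' @export
setMethod("epochRate", "EpochSet", function(x) nrow(x@events) / x@traceDuration)

#' @rdname accessors
#' @export
setMethod("meanEpochDuration", "EpochSet", function(x) {
  if (!nrow(x@events)) return(NA_real_)
  mean(x@events$end_s - x@events$start_s)
})

setMethod("show", "EpochSet", function(object) {
  bd <- if (all(is.na(object@band))) "broadband"
        else sprintf("%.3g-%.3g Hz", object@band[1], object@band[2])
  cat(sprintf("EpochSet (%s, %s): %d events in %.1f s (rate %.4g /s, mean duration %s)\n",
              object@method, bd, nrow(object@events), object@traceDuration,
              epochRate(object),
              if (nrow(object@events)) sprintf("%.3g s", meanEpochDuration(object))
              else "undefined"))
})

setMethod("show", "ThresholdModel", function(object) {
  cat(sprintf("ThresholdModel: mode %.4f, sigma %.4f, k %.3g -> threshold %.4f (%d bins)\n",
              object@mode, object@sigma, object@k, object@threshold, object@nBins))
})

#' @rdname accessors
#' @export
setMethod("detectionThreshold", "ThresholdModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("freqCenters", "Scalogram", function(x) x@freqs)

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram: %d time points at %g Hz x %d frequencies (%.3g-%.3g Hz), %g cycles\n",
              nrow(object@magnitude), object@analysisFs, length(object@freqs),
              min(object@freqs), max(object@freqs), object@cycles))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d frames at %g Hz x %d bins (df %g Hz), window %g s, overlap %g\n",
              nrow(object@magnitude), object@frameFs, length(object@freqs),
              if (length(object@freqs) > 1) object@freqs[2] - object@freqs[1] else NA,
              object@windowS, object@overlap))
})

#' @rdname accessors
#' @export
setMethod("channelLabels", "GridRecording", function(x) names(x@channels))

#' @rdname accessors
#' @export
setMethod("getChannel", "GridRecording", function(x, label) {
  if (!label %in% names(x@channels))
    stop("no channel labelled '", label, "'")
  x@channels[[label]]
})

#' @rdname accessors
#' @export
setMethod("samplingRate", "GridRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("duration", "GridRecording", function(x) duration(x@channels[[1]]))

setMethod("show", "GridRecording", function(object) {
  cat(sprintf("GridRecording: %d channels at %g Hz, %.1f s [%s...]\n",
              length(object@channels), object@fs, duration(object),
              paste(utils::head(names(object@channels), 4), collapse = ", ")))
})

#' Construct a GridRecording
#'
#' @param channels named list of [SignalTrace-class] objects (or numeric
#'   vectors, converted using \code{fs}).
#' @param fs shared sampling rate in Hz; taken from the first trace when
#'   omitted.
#' @param units amplitude units.
#' @param metadata free-form metadata list.
#' @return a [GridRecording-class].
#' @export
GridRecording <- function(channels, fs = NULL, units = "uV", metadata = list()) {
  if (is.null(names(channels)))
    names(channels) <- as.character(seq_along(channels))
  channels <- lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    if (is(ch, "SignalTrace")) ch
    else SignalTrace(ch, fs = fs, label = names(channels)[i])
  })
  names(channels) <- vapply(channels, traceLabel, "")
  if (is.null(fs)) fs <- channels[[1]]@fs
  new("GridRecording", channels = channels, fs = fs, units = units,
      metadata = metadata)
}
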