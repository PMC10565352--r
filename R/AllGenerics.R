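#' Accessors for wavepoch classes
#'
#' Accessor generics for the core containers: sample vector, sampling rate,
#' start time, channel label and duration of a [SignalTrace-class]; events
#' table, counts, rate and mean duration of an [EpochSet-class]; frequency
#' centers of a [Scalogram-class].
#'
#' @param x an object.
#' @return the corresponding slot or derived quantity.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("traceLabel", function(x) standardGeneric("traceLabel"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("epochRate", function(x) standardGeneric("epochRate"))

#' @rdname accessors
#' @export
setGeneric("meanEpochDuration", function(x) standardGeneric("meanEpochDuration"))

#' @rdname accessors
#' @export
setGeneric("freqCenters", function(x) standardGeneric("freqCenters"))

#' @rdname accessors
#' @export
setGeneric("detectionThreshold", function(x) standardGeneric("detectionThreshold"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, label) standardGeneric("getChannel"))
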