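#' Read a recording from CSV
#'
#' The CSV layout is one column per channel with a header row of channel
#' labels, preceded by a comment line declaring the sampling rate, e.g.
#' \code{# fs_hz=12500}.  Alternatively the rate can be passed via
#' \code{fs}.  An optional \code{units} key may follow on the same comment
#' line (\code{# fs_hz=12500 units=uV}).
#'
#' @param path file path.
#' @param fs sampling rate in Hz; overrides the header line when given.
#' @return a [SignalTrace-class] for a single-column file, otherwise a
#'   [GridRecording-class].
#' @export
readRecording <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  units <- "uV"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("fs_hz\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) {
      hdrFs <- as.numeric(m[2])
      if (is.null(fs)) fs <- hdrFs
    }
    mu <- regmatches(first, regexec("units\\s*=\\s*(\\S+)", first))[[1]]
    if (length(mu) == 2) units <- mu[2]
  }
  if (is.null(fs))
    stop("no sampling rate: add a '# fs_hz=...' header line or pass fs")
  dat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!ncol(dat)) stop("no channels found in ", path)
  if (ncol(dat) == 1L)
    return(SignalTrace(dat[[1]], fs = fs, label = names(dat)[1]))
  GridRecording(as.list(dat), fs = fs, units = units)
}

#' Write a recording to CSV
#'
#' Writes the layout read by [readRecording()]: a \code{# fs_hz=...} header
#' line followed by one column per channel.
#'
#' @param x a [SignalTrace-class] or [GridRecording-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRecording <- function(x, path) {
  if (is(x, "SignalTrace")) {
    dat <- stats::setNames(
      data.frame(x@samples),
      if (nzchar(x@label)) x@label else "signal")
    fs <- x@fs
    units <- "uV"
  } else if (is(x, "GridRecording")) {
    dat <- as.data.frame(lapply(x@channels, samples), check.names = FALSE)
    fs <- x@fs
    units <- x@units
  } else stop("x must be a SignalTrace or GridRecording")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g units=%s", fs, units), con)
  utils::write.csv(dat, con, row.names = FALSE)
  invisible(path)
}

.epochHeader <- c("channel", "method", "band_lo_hz", "band_hi_hz",
                  "start_s", "end_s", "peak_norm")

#' Write epoch tables to CSV
#'
#' Deterministic CSV with header
#' \code{channel,method,band_lo_hz,band_hi_hz,start_s,end_s,peak_norm},
#' rows ordered by channel then onset; times carry millisecond precision or
#' better.
#'
#' @param x an [EpochSet-class] or a list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEpochs <- function(x, path) {
  if (is(x, "EpochSet")) x <- list(x)
  tabs <- lapply(x, function(es) {
    ev <- es@events
    data.frame(channel = rep(es@channel, nrow(ev)),
               method = rep(es@method, nrow(ev)),
               band_lo_hz = rep(es@band[1], nrow(ev)),
               band_hi_hz = rep(es@band[2], nrow(ev)),
               start_s = round(ev$start_s, 6),
               end_s = round(ev$end_s, 6),
               peak_norm = round(ev$peak_norm, 6))
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab)) tab <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(.epochHeader)), .epochHeader))
  tab <- tab[order(tab$channel, tab$start_s), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read an epoch table written by [writeEpochs()]
#'
#' @param path CSV path.
#' @return data.frame with the epoch-table columns.
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path)
  missing <- setdiff(.epochHeader, names(tab))
  if (length(missing))
    stop("not an epoch table; missing columns: ",
         paste(missing, collapse = ", "))
  tab
}
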