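#' Fit the baseline threshold of a normalized band trace
#'
#' The histogram of a normalized band-average trace shows a Gaussian-like
#' baseline bulk with a right skew contributed by sparse epochs.  The bulk
#' is characterized by its half-maximum interval on the (moving-average
#' smoothed) histogram: the bulk center \code{mode} is the interval's
#' midpoint and the spread \code{sigma} is its width divided by 2.3548,
#' with the width inflation of the smoothing window deconvolved.  Both
#' recover the exact parameters of a truly Gaussian baseline while being
#' insensitive to the event-contaminated right tail.  The detection
#' threshold is \code{mode + k * sigma}, clipped to 1.
#'
#' @param x a normalized [BandAverageTrace-class] or numeric vector with
#'   values in [0, 1].
#' @param nBins number of equal-width histogram bins on [0, 1] (default 100).
#' @param k threshold multiplier (default 3).
#' @param smoothBins width, in bins, of the moving average applied to the
#'   histogram counts before locating the peak (default 5; 1 disables).
#' @return a [ThresholdModel-class].
#' @export
fitBaselineThreshold <- function(x, nBins = 100, k = 3, smoothBins = 5) {
  vals <- if (is(x, "BandAverageTrace")) x@values else as.numeric(x)
  if (length(vals) < 100) stop("fewer than 100 samples")
  if (max(vals) - min(vals) < 1e-12) stop("degenerate baseline (constant trace)")
  if (min(vals) < -1e-9 || max(vals) > 1 + 1e-9)
    stop("values must lie in [0, 1]; normalize first")
  h <- graphics::hist(pmin(pmax(vals, 0), 1),
                      breaks = seq(0, 1, length.out = nBins + 1), plot = FALSE)
  cnt <- h$counts
  if (smoothBins > 1) {
    sm <- as.numeric(stats::filter(cnt, rep(1 / smoothBins, smoothBins),
                                   sides = 2))
    cnt <- ifelse(is.na(sm), cnt, sm)
  }
  i <- which.max(cnt)           # ties broken toward the lower bin
  level <- cnt[i] / 2
  bw <- 1 / nBins
  ri <- i
  while (ri < nBins && cnt[ri + 1] >= level) ri <- ri + 1
  li <- i
  while (li > 1 && cnt[li - 1] >= level) li <- li - 1
  # half-maximum crossings by linear interpolation between bin midpoints
  xr <- if (ri < nBins)
    h$mids[ri] + (cnt[ri] - level) / max(cnt[ri] - cnt[ri + 1], 1e-12) * bw
  else 1
  xl <- if (li > 1)
    h$mids[li] - (cnt[li] - level) / max(cnt[li] - cnt[li - 1], 1e-12) * bw
  else 0
  mu <- (xl + xr) / 2
  # deconvolve the moving-average width: var of a length-w boxcar is
  # (w^2 - 1) / 12 bins^2
  sig2 <- ((xr - xl) / 2.3548)^2 - bw^2 * (smoothBins^2 - 1) / 12
  sigma <- max(sqrt(max(sig2, 0)), bw)
  new("ThresholdModel", mode = mu, sigma = sigma, k = k,
      threshold = min(mu + k * sigma, 1), nBins = as.integer(nBins))
}

#' Segment suprathreshold runs into epoch events
#'
#' Maximal runs above the threshold are located; runs separated by gaps
#' shorter than \code{mergeGapS} are merged first (they are considered part
#' of one larger oscillation epoch), then merged runs shorter than
#' \code{minDurationS} are discarded (a run of exactly the minimum duration
#' is kept).  Events are half-open intervals in seconds.
#'
#' @param x a normalized [BandAverageTrace-class] or numeric vector.
#' @param threshold scalar in (0, 1], or a [ThresholdModel-class].
#' @param fs sampling rate (required for numeric input).
#' @param minDurationS minimum epoch duration, seconds (default 0.5).
#' @param mergeGapS gap below which adjacent runs merge, seconds (default 0.5).
#' @param band,method,channel metadata stored in the result.
#' @return an [EpochSet-class].
#' @export
segmentEpochs <- function(x, threshold, fs = NULL, minDurationS = 0.5,
                          mergeGapS = 0.5, band = c(NA_real_, NA_real_),
                          method = "wavelet", channel = "") {
  if (is(x, "BandAverageTrace")) {
    vals <- x@values; fs <- x@fs
    if (all(is.na(band))) band <- x@band
  } else {
    if (is.null(fs)) stop("fs is required for a numeric input")
    vals <- as.numeric(x)
  }
  if (is(threshold, "ThresholdModel")) threshold <- threshold@threshold
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- length(vals)
  iv <- .maskToIntervals(vals > threshold, fs)
  iv <- .mergeIntervals(iv, mergeGapS)
  keep <- (iv[, 2] - iv[, 1]) >= minDurationS - 1e-9
  iv <- iv[keep, , drop = FALSE]
  peak <- vapply(seq_len(nrow(iv)), function(r) {
    i0 <- max(1L, floor(iv[r, 1] * fs) + 1L)
    i1 <- min(n, ceiling(iv[r, 2] * fs))
    max(vals[i0:i1])
  }, 1)
  new("EpochSet",
      events = data.frame(start_s = iv[, 1], end_s = iv[, 2],
                          peak_norm = peak),
      traceDuration = n / fs, band = band, method = method, channel = channel)
}

#' Detect oscillation epochs in one frequency band
#'
#' The full single-band pipeline: resample to the analysis rate, Morlet
#' transform on the 0.25-octave grid covering the band, per-time band
#' average, segment-wise normalization, histogram threshold, and run
#' segmentation with the duration and merge rules.  The band is specified
#' either directly as \code{band = c(lo, hi)} or as an octave-wide (by
#' default) window centered on \code{centerHz}.
#'
#' @param trace a [SignalTrace-class] (any sampling rate >= analysisFs).
#' @param centerHz band center, Hz (used when \code{band} is NULL).
#' @param band explicit c(lo, hi) band bounds in Hz.
#' @param widthOctaves width of the centered band, octaves (default 1).
#' @param analysisFs analysis sampling rate, Hz (default 256).
#' @param cycles Morlet cycle parameter.
#' @param stepOctaves grid spacing within the band.
#' @param segmentS normalization segment, seconds.
#' @param nBins,k,smoothBins threshold-fit parameters
#'   (see [fitBaselineThreshold()]).
#' @param minDurationS,mergeGapS segmentation rules (see [segmentEpochs()]).
#' @return an [EpochSet-class] with method tag "wavelet".
#' @export
detectBand <- function(trace, centerHz = NULL, band = NULL, widthOctaves = 1,
                       analysisFs = 256, cycles = 6, stepOctaves = 0.25,
                       segmentS = 30, nBins = 100, k = 3, smoothBins = 5,
                       minDurationS = 0.5, mergeGapS = 0.5) {
  stopifnot(is(trace, "SignalTrace"))
  if (is.null(band)) {
    if (is.null(centerHz)) stop("either centerHz or band must be given")
    band <- centerHz * 2^(c(-1, 1) * widthOctaves / 2)
  }
  if (band[2] >= analysisFs / 2)
    stop("band upper edge at or above the analysis Nyquist")
  tr <- if (trace@fs > analysisFs) resampleForAnalysis(trace, analysisFs) else trace
  grid <- buildFrequencyGrid(band[1], band[2], stepOctaves)
  sc <- cwtMorlet(tr, grid, cycles)
  ba <- bandAverage(sc, band[1], band[2])
  nb <- normalizeSegmentwise(ba, segmentS = segmentS)
  tm <- fitBaselineThreshold(nb, nBins = nBins, k = k, smoothBins = smoothBins)
  segmentEpochs(nb, tm, minDurationS = minDurationS, mergeGapS = mergeGapS,
                band = band, method = "wavelet", channel = trace@label)
}

#' Scan all frequency bands of a grid
#'
#' Runs the band-detection pipeline sequentially for every grid center,
#' using an octave-wide (by default) window around each center.  The
#' resample and Morlet transform are computed once and reused across bands.
#'
#' @param trace a [SignalTrace-class].
#' @param grid frequency grid centers (default [buildFrequencyGrid()]).
#' @param widthOctaves band width per center, octaves.
#' @param analysisFs,cycles,segmentS,nBins,k,smoothBins,minDurationS,mergeGapS
#'   as in [detectBand()].
#' @return named list (names = centers) of [EpochSet-class] objects.
#' @export
panFrequencyScan <- function(trace, grid = buildFrequencyGrid(),
                             widthOctaves = 1, analysisFs = 256, cycles = 6,
                             segmentS = 30, nBins = 100, k = 3,
                             smoothBins = 5, minDurationS = 0.5,
                             mergeGapS = 0.5) {
  stopifnot(is(trace, "SignalTrace"))
  grid <- sort(as.numeric(grid))
  tr <- if (trace@fs > analysisFs) resampleForAnalysis(trace, analysisFs) else trace
  sc <- cwtMorlet(tr, grid, cycles)
  out <- vector("list", length(grid))
  names(out) <- as.character(grid)
  for (i in seq_along(grid)) {
    lo <- grid[i] * 2^(-widthOctaves / 2)
    hi <- grid[i] * 2^(widthOctaves / 2)
    ba <- bandAverage(sc, lo, hi)
    nb <- normalizeSegmentwise(ba, segmentS = segmentS)
    tm <- tryCatch(fitBaselineThreshold(nb, nBins = nBins, k = k,
                                        smoothBins = smoothBins),
                   error = function(e) NULL)
    out[[i]] <- if (is.null(tm)) {
      new("EpochSet", events = data.frame(start_s = numeric(0),
                                          end_s = numeric(0),
                                          peak_norm = numeric(0)),
          traceDuration = duration(tr), band = c(lo, hi),
          method = "wavelet", channel = trace@label)
    } else {
      segmentEpochs(nb, tm, minDurationS = minDurationS,
                    mergeGapS = mergeGapS, band = c(lo, hi),
                    method = "wavelet", channel = trace@label)
    }
  }
  out
}

#' Pool per-band events into a frequency class
#'
#' Events from all bands whose window intersects the class range (e.g. low =
#' 0.5-8 Hz, gamma = 30-50 Hz) are merged by time-interval union, so one
#' physical epoch detected in several adjacent bands counts once; pooled
#' events are re-checked against the minimum duration.
#'
#' @param epochSets list of [EpochSet-class] objects (e.g. from
#'   [panFrequencyScan()]).
#' @param classRange c(lo, hi) class bounds in Hz.
#' @param minDurationS minimum pooled-event duration, seconds.
#' @return an [EpochSet-class] with the class range as its band.
#' @export
poolClassEvents <- function(epochSets, classRange, minDurationS = 0.5) {
  if (length(classRange) != 2 || classRange[1] >= classRange[2])
    stop("classRange must be c(lo, hi) with lo < hi")
  inClass <- vapply(epochSets, function(es)
    !any(is.na(es@band)) && es@band[1] < classRange[2] &&
      es@band[2] > classRange[1], TRUE)
  sets <- epochSets[inClass]
  dur <- if (length(epochSets)) epochSets[[1]]@traceDuration else 0
  chan <- if (length(epochSets)) epochSets[[1]]@channel else ""
  evs <- do.call(rbind, lapply(sets, function(es) es@events))
  if (is.null(evs) || !nrow(evs)) {
    return(new("EpochSet",
               events = data.frame(start_s = numeric(0), end_s = numeric(0),
                                   peak_norm = numeric(0)),
               traceDuration = dur, band = classRange, method = "wavelet",
               channel = chan))
  }
  ord <- order(evs$start_s)
  iv <- cbind(evs$start_s[ord], evs$end_s[ord])
  ## union: merge whenever intervals touch or overlap (gap <= 0)
  merged <- matrix(NA_real_, nrow(iv), 3)
  k <- 1L
  merged[1, ] <- c(iv[1, ], evs$peak_norm[ord][1])
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= merged[k, 2] + 1e-12) {
      merged[k, 2] <- max(merged[k, 2], iv[i, 2])
      merged[k, 3] <- max(merged[k, 3], evs$peak_norm[ord][i])
    } else {
      k <- k + 1L
      merged[k, ] <- c(iv[i, ], evs$peak_norm[ord][i])
    }
  }
  merged <- merged[seq_len(k), , drop = FALSE]
  keep <- (merged[, 2] - merged[, 1]) >= minDurationS - 1e-9
  merged <- merged[keep, , drop = FALSE]
  new("EpochSet",
      events = data.frame(start_s = merged[, 1], end_s = merged[, 2],
                          peak_norm = merged[, 3]),
      traceDuration = dur, band = classRange, method = "wavelet",
      channel = chan)
}
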