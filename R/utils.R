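#' Root-mean-square amplitude
#'
#' @param x numeric vector.
#' @return sqrt(mean(x^2)).
#' @export
rms <- function(x) sqrt(mean(x^2))

## Fourier-domain resampling: keep the lowest min(n, nOut) %/% 2 positive and
## negative frequency bins and invert at the new length.  Exact for band-
## limited content; out-of-band content is removed entirely.
.fftResample <- function(x, nOut) {
  n <- length(x)
  if (nOut == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = nOut)
  half <- min(n, nOut) %/% 2
  Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
  if (half > 0)
    Y[(nOut - half + 1):nOut] <- X[(n - half + 1):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

## Analytic signal via the frequency-domain Hilbert construction.
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Sliding-window mean with truncated (shrinking) edge windows; length
## preserving.  w is the window length in samples.
.slidingMean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0L, i - ceiling(w / 2))
  hi <- pmin(n, i + floor(w / 2))
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

## Merge half-open intervals given as a 2-column matrix (start, end), sorted
## by start: intervals closer than mergeGap are joined; gaps of exactly
## mergeGap are NOT joined (events "less than" the gap apart form one epoch).
.mergeIntervals <- function(iv, mergeGap = 0) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(iv), 2)
  k <- 1L
  out[1, ] <- iv[1, ]
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] - out[k, 2] < mergeGap - 1e-12) {
      out[k, 2] <- max(out[k, 2], iv[i, 2])
    } else {
      k <- k + 1L
      out[k, ] <- iv[i, ]
    }
  }
  out[seq_len(k), , drop = FALSE]
}

## Suprathreshold runs of a logical mask -> half-open intervals in seconds.
.maskToIntervals <- function(mask, fs, t0 = 0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(t0 + (starts[keep] - 1) / fs, t0 + ends[keep] / fs)
}

#' Full width at half prominence of a spectrum
#'
#' Width, in Hz, of the main peak of a magnitude spectrum measured at half
#' its prominence (peak height above the spectrum minimum).  Crossings are
#' located by linear interpolation; if a side never crosses, the spectrum
#' edge is used.
#'
#' @param freqs frequency axis, Hz (ascending).
#' @param mag magnitudes.
#' @return width in Hz.
#' @export
spectralSpread <- function(freqs, mag) {
  stopifnot(length(freqs) == length(mag), length(mag) >= 3)
  pk <- which.max(mag)
  level <- mag[pk] - (mag[pk] - min(mag)) / 2
  interp <- function(i, j) {
    # crossing of `level` between points i and j
    if (mag[i] == mag[j]) return(freqs[j])
    freqs[i] + (level - mag[i]) / (mag[j] - mag[i]) * (freqs[j] - freqs[i])
  }
  fl <- freqs[1]
  if (pk > 1) for (i in pk:2) {
    if (mag[i - 1] < level) { fl <- interp(i, i - 1); break }
  }
  fr <- freqs[length(freqs)]
  if (pk < length(mag)) for (i in pk:(length(mag) - 1)) {
    if (mag[i + 1] < level) { fr <- interp(i, i + 1); break }
  }
  fr - fl
}

## Draw independent sub-stream seeds from a top-level seed.
.subSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
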