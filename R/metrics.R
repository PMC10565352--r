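#' Score detections against ground truth
#'
#' Detections are matched to truth intervals one-to-one by onset order: a
#' detection is a true positive if it overlaps an as-yet-unmatched truth
#' interval (any positive overlap by default, or at least half the truth
#' duration with \code{rule = "half"}).  Unmatched detections are false
#' positives; unmatched truths are false negatives.  \code{recovered} counts
#' truth intervals overlapped by at least one detection regardless of the
#' one-to-one constraint (the recovered-truth sensitivity; a single merged
#' detection spanning two truths recovers both but scores one TP).
#'
#' @param detected an [EpochSet-class] or a data.frame with \code{start_s},
#'   \code{end_s}.
#' @param truth data.frame with columns \code{onset_s}, \code{offset_s}
#'   (as returned by the simulator).
#' @param rule overlap rule: \code{"any"} (default) or \code{"half"}.
#' @return list with \code{nTruth}, \code{tp}, \code{fp}, \code{fn},
#'   \code{sensitivity} (= tp/nTruth), \code{recovered},
#'   \code{recoveredFraction}, and \code{fpPerMin}.
#' @export
scoreDetection <- function(detected, truth, rule = c("any", "half")) {
  rule <- match.arg(rule)
  if (is(detected, "EpochSet")) {
    ev <- detected@events
    dur <- detected@traceDuration
  } else {
    ev <- detected
    dur <- NA_real_
  }
  nTruth <- nrow(truth)
  matched <- rep(FALSE, nTruth)
  covered <- rep(FALSE, nTruth)
  tp <- 0L
  if (nrow(ev)) {
    ord <- order(ev$start_s)
    for (i in ord) {
      ol <- pmin(truth$offset_s, ev$end_s[i]) - pmax(truth$onset_s, ev$start_s[i])
      need <- if (rule == "any") 1e-9 else (truth$offset_s - truth$onset_s) / 2
      hit <- ol >= need
      covered <- covered | hit
      j <- which(hit & !matched)
      if (length(j)) {
        matched[j[1]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(ev) - tp
  fn <- nTruth - tp
  list(nTruth = nTruth, tp = tp, fp = fp, fn = fn,
       sensitivity = if (nTruth > 0) tp / nTruth else NA_real_,
       recovered = sum(covered),
       recoveredFraction = if (nTruth > 0) mean(covered) else NA_real_,
       fpPerMin = if (is.finite(dur) && dur > 0) fp / (dur / 60) else NA_real_)
}

#' Epoch rate and mean duration
#'
#' @param epochSet an [EpochSet-class].
#' @return list with \code{n}, \code{rate} (epochs per second over the trace
#'   duration) and \code{meanDurationS} (NA for an empty set).
#' @export
epochStats <- function(epochSet) {
  stopifnot(is(epochSet, "EpochSet"))
  if (epochSet@traceDuration <= 0) stop("trace duration must be positive")
  list(n = nEpochs(epochSet), rate = epochRate(epochSet),
       meanDurationS = meanEpochDuration(epochSet))
}

#' Low:high frequency epoch-number ratio (LHR)
#'
#' Single modulation index: the number of pooled low-frequency (0.5-8 Hz)
#' epochs divided by the number of gamma (30-50 Hz) epochs in the same
#' recording.  Undefined (flagged) when the high-frequency count is zero.
#'
#' @param low low-class [EpochSet-class] or a count.
#' @param high high-class [EpochSet-class] or a count.
#' @return list with \code{lowCount}, \code{highCount}, \code{ratio},
#'   \code{undefined}.
#' @export
lhr <- function(low, high) {
  nl <- if (is(low, "EpochSet")) nEpochs(low) else as.numeric(low)
  nh <- if (is(high, "EpochSet")) nEpochs(high) else as.numeric(high)
  list(lowCount = nl, highCount = nh,
       ratio = if (nh > 0) nl / nh else NA_real_,
       undefined = nh == 0)
}

#' Cohen's effect size d
#'
#' \code{cohensD} is the direct form: the absolute difference between means
#' divided by the pooled standard deviation.  \code{cohensDGroups} computes
#' it from samples, pooling as
#' sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)) for independent groups or
#' sqrt((s1^2 + s2^2) / 2) for paired designs.
#'
#' @param meanDiff difference between the group means.
#' @param sdPooled pooled standard deviation (> 0).
#' @return the effect size d (nonnegative).
#' @examples
#' cohensD(6.7, 3.69)    # 1.82
#' cohensD(9.52, 4.61)   # 2.06
#' @export
cohensD <- function(meanDiff, sdPooled) {
  if (sdPooled <= 0) stop("pooled standard deviation must be > 0")
  abs(meanDiff) / sdPooled
}

#' @rdname cohensD
#' @param a,b numeric sample vectors.
#' @param design \code{"independent"} or \code{"paired"} pooling convention.
#' @export
cohensDGroups <- function(a, b, design = c("independent", "paired")) {
  design <- match.arg(design)
  n1 <- length(a); n2 <- length(b)
  s1 <- stats::var(a); s2 <- stats::var(b)
  sp <- if (design == "independent")
    sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  else sqrt((s1 + s2) / 2)
  cohensD(mean(b) - mean(a), sp)
}

#' Compare epoch rates between two conditions
#'
#' For paired per-unit rates (e.g. per-slice rates at baseline and after an
#' intervention): percent change, Cohen's d (paired pooling), paired t test,
#' Wilcoxon signed-rank test, and Welch's unequal-variance t test treating
#' the vectors as independent groups (used for between-genotype contrasts).
#'
#' @param a,b paired numeric vectors (condition A = baseline, B = treated).
#' @return list with \code{percentChange} (mean of per-unit
#'   100 * (B - A) / A), \code{cohensD}, \code{pairedT}, \code{wilcoxon},
#'   \code{welch} (each an \code{htest}).
#' @export
compareConditions <- function(a, b) {
  if (length(a) != length(b)) stop("conditions must be paired")
  if (length(a) < 2) stop("at least two pairs required")
  pc <- if (all(a > 0)) mean(100 * (b - a) / a) else NA_real_
  d <- if (stats::sd(a) > 0 || stats::sd(b) > 0)
    cohensDGroups(a, b, "paired") else 0
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  list(percentChange = pc,
       cohensD = d,
       pairedT = safe(stats::t.test(b, a, paired = TRUE)),
       wilcoxon = safe(stats::wilcox.test(b, a, paired = TRUE, exact = FALSE)),
       welch = safe(stats::t.test(b, a, var.equal = FALSE)))
}

#' Binned time course of event rates
#'
#' Event counts in consecutive bins, normalized to rates; a partial final
#' bin is normalized by its actual length.
#'
#' @param eventTimes numeric vector of event onset times, seconds.
#' @param totalDurationS total recording duration, seconds.
#' @param binS bin width, seconds (default 600, i.e. 10 min).
#' @return data.frame with \code{binStart}, \code{binEnd}, \code{count},
#'   \code{rate} (events per second).
#' @export
timeCourse <- function(eventTimes, totalDurationS, binS = 600) {
  if (binS <= 0) stop("binS must be > 0")
  nBins <- max(1L, ceiling(totalDurationS / binS - 1e-9))
  starts <- (seq_len(nBins) - 1) * binS
  ends <- pmin(starts + binS, totalDurationS)
  counts <- vapply(seq_along(starts), function(i)
    sum(eventTimes >= starts[i] & eventTimes < ends[i]), 1L)
  data.frame(binStart = starts, binEnd = ends, count = counts,
             rate = counts / (ends - starts))
}
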