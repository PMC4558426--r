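#' Instantaneous frequency of a spike train
#'
#' The instantaneous frequency (IF) is the reciprocal of each inter-spike
#' interval. Each IF sample is stamped at the time of the second spike of the
#' pair, so every value is a causal measurement available at that moment.
#'
#' @param train a [SpikeTrain-class].
#' @return data.frame with columns `time` (s) and `if_hz` (Hz); one row per
#'   consecutive spike pair (empty for fewer than two spikes).
#' @examples
#' instantaneousFrequency(SpikeTrain(c(0, 0.5, 0.75)))   # 2 Hz, 4 Hz
#' @export
instantaneousFrequency <- function(train) {
  sp <- train@times
  if (length(sp) < 2L)
    return(data.frame(time = numeric(), if_hz = numeric()))
  isi <- diff(sp)
  if (any(isi == 0)) stop("duplicate spike times")
  data.frame(time = sp[-1L], if_hz = 1 / isi)
}

#' Bin spike-train activity into 1-s windows
#'
#' Per stimulus bin, computes the median instantaneous frequency of the IF
#' samples whose timestamp falls inside the bin (missing when the bin holds
#' none -- the median of an empty set is undefined, and zero would bias
#' suppression fits) and the mean firing rate (spike count divided by the bin
#' width; zero for empty bins, giving complete coverage).
#'
#' @param train a [SpikeTrain-class].
#' @param bins data.frame with a `bin_start` column (from [binStimulus()]),
#'   contiguous bins of width `binWidth`.
#' @param binWidth bin width in seconds (default 1).
#' @return data.frame with columns `bin_start`, `median_if` (Hz or NA),
#'   `mean_rate` (APs/s) and `nif` (percent; NA until [normalizeNif()]).
#' @examples
#' bins <- data.frame(bin_start = 0:4)
#' binActivity(SpikeTrain(seq(0.05, 0.95, 0.1)), bins)[1, ]
#' @export
binActivity <- function(train, bins, binWidth = 1) {
  starts <- bins$bin_start
  if (length(starts) > 1L &&
      max(abs(diff(starts) - binWidth)) > 1e-8)
    stop("bins must be contiguous with width binWidth")
  edges <- c(starts, starts[length(starts)] + binWidth)
  sp <- train@times
  counts <- if (length(sp))
    tabulate(findInterval(sp, edges, rightmost.closed = FALSE,
                          left.open = FALSE),
             nbins = length(starts) + 1L)[seq_along(starts)]
  else rep(0L, length(starts))
  iff <- instantaneousFrequency(train)
  medianIf <- rep(NA_real_, length(starts))
  if (nrow(iff)) {
    b <- findInterval(iff$time, edges)
    inside <- b >= 1L & b <= length(starts)
    if (any(inside)) {
      agg <- tapply(iff$if_hz[inside], b[inside], median)
      medianIf[as.integer(names(agg))] <- agg
    }
  }
  data.frame(bin_start = starts, median_if = medianIf,
             mean_rate = counts / binWidth, nif = NA_real_)
}

#' Normalize binned activity to the pre-stimulus baseline (nIF)
#'
#' The mean of the per-bin median IF over the `baselineLen` seconds before
#' stimulus onset defines 100 percent; every bin's nIF is its median IF
#' expressed relative to that baseline. Twice the standard deviation of the
#' baseline-window nIF is used as the noise level of the resting activity.
#'
#' @param activity data.frame from [binActivity()].
#' @param onset stimulus onset, seconds.
#' @param baselineLen baseline window length, seconds (default 10).
#' @param minBins minimum number of baseline bins with a defined median IF
#'   (default 5); recordings below this are rejected rather than
#'   extrapolated.
#' @return list with elements `activity` (input with `nif` filled, percent)
#'   and `baseline` (a [BaselineStats-class]).
#' @examples
#' bins <- data.frame(bin_start = 0:19)
#' act <- binActivity(SpikeTrain(seq(0.005, 20, 0.025)), bins)
#' res <- normalizeNif(act, onset = 10)
#' res$baseline
#' @export
normalizeNif <- function(activity, onset, baselineLen = 10, minBins = 5) {
  inWindow <- activity$bin_start >= onset - baselineLen &
    activity$bin_start < onset
  base <- activity$median_if[inWindow]
  base <- base[!is.na(base)]
  if (length(base) < minBins)
    stop(sprintf("insufficient baseline: %d of >= %d bins with a median IF",
                 length(base), minBins))
  baseMean <- mean(base)
  if (baseMean <= 0) stop("baseline median IF is zero")
  activity$nif <- 100 * activity$median_if / baseMean
  sdNif <- sd(100 * base / baseMean)
  baseline <- new("BaselineStats",
                  windowStart = onset - baselineLen, windowEnd = onset,
                  meanNif = 100, sdNif = sdNif, noiseLevel = 2 * sdNif,
                  meanRateHz = baseMean, nBins = length(base))
  list(activity = activity, baseline = baseline)
}
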