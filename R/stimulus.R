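#' Gaussian smoothing of a temperature trace
#'
#' Discrete Gaussian convolution with a kernel of standard deviation `sigma`
#' seconds (converted to samples via the median sampling interval). The
#' kernel is truncated at +/- 4 sigma; at the edges the kernel is
#' renormalized over the available samples, so constant traces are preserved
#' exactly. `sigma = 0` is the identity.
#'
#' @param trace a [TemperatureTrace-class].
#' @param sigma kernel standard deviation in seconds (>= 0; default 0.5).
#' @return a smoothed [TemperatureTrace-class] on the same time base.
#' @examples
#' tr <- TemperatureTrace(seq(0, 10, 0.25), 25 - 0.1 * seq(0, 10, 0.25))
#' sm <- gaussSmooth(tr, 0.5)
#' max(abs(traceTemps(sm)[10:30] - traceTemps(tr)[10:30]))  # affine preserved
#' @export
gaussSmooth <- function(trace, sigma = 0.5) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(trace)
  dt <- median(diff(trace@times))
  sigmaSamples <- sigma / dt
  h <- ceiling(4 * sigmaSamples)
  w <- dnorm(seq(-h, h), sd = sigmaSamples)
  x <- trace@temps
  n <- length(x)
  # zero-padded convolution of the signal and of the weight mass, so edge
  # bins are renormalized over the samples actually present
  num <- convolve(c(rep(0, h), x, rep(0, h)), w, type = "filter")
  den <- convolve(c(rep(0, h), rep(1, n), rep(0, h)), w, type = "filter")
  TemperatureTrace(trace@times, num / den)
}

#' Bin a temperature trace into 1-s stimulus descriptors
#'
#' Cuts the trace into contiguous half-open bins `[start, start + width)`
#' anchored at the first sample time. Per bin, `mean_temp` is the arithmetic
#' mean of the samples and `changing_rate` the least-squares slope of
#' temperature on time (exact for affine signals). Bins with fewer than two
#' samples are dropped.
#'
#' @param trace a [TemperatureTrace-class] (typically Gauss-smoothed first).
#' @param binWidth bin width in seconds (default 1).
#' @return a data.frame with columns `bin_start` (s), `mean_temp` (degC) and
#'   `changing_rate` (degC/s).
#' @examples
#' tt <- seq(0, 10, 0.25)
#' b <- binStimulus(TemperatureTrace(tt, 25 - 0.1 * tt))
#' b$changing_rate[2]   # -0.1 on a noiseless ramp
#' @export
binStimulus <- function(trace, binWidth = 1) {
  times <- trace@times
  temps <- trace@temps
  if (times[length(times)] - times[1] < 2 * binWidth)
    stop("trace too short: need at least two bins")
  idx <- floor((times - times[1]) / binWidth)
  counts <- tabulate(idx + 1L)
  full <- which(counts >= 2L) - 1L         # bins with < 2 samples are dropped
  sel <- idx %in% full
  f <- factor(idx[sel], levels = full)
  tsplit <- split(times[sel], f)
  xsplit <- split(temps[sel], f)
  meanTemp <- vapply(xsplit, mean, numeric(1))
  slope <- mapply(function(tt, xx) {
    tc <- tt - mean(tt)
    sum(tc * xx) / sum(tc * tc)
  }, tsplit, xsplit)
  data.frame(
    bin_start = times[1] + full * binWidth,
    mean_temp = unname(meanTemp),
    changing_rate = unname(slope),
    row.names = NULL
  )
}

#' Detect stimulus onset from binned stimulus descriptors
#'
#' Returns the start time of the first bin whose absolute changing rate is at
#' least `rateFloor` and which begins a run of at least `runLength`
#' consecutive such bins. The run-length requirement suppresses single-bin
#' noise triggers. When the stimulation controller supplies the onset
#' directly, pass it downstream instead of calling this.
#'
#' @param binned data.frame from [binStimulus()].
#' @param rateFloor minimum absolute changing rate, degC/s (> 0).
#' @param runLength required run of consecutive supra-floor bins (default 3).
#' @return onset time in seconds.
#' @examples
#' tt <- seq(0, 40, 0.25)
#' tr <- TemperatureTrace(tt, ifelse(tt < 20, 25, 25 - 0.1 * (tt - 20)))
#' detectOnset(binStimulus(tr), rateFloor = 0.02)
#' @export
detectOnset <- function(binned, rateFloor = 0.005, runLength = 3) {
  if (rateFloor <= 0) stop("rateFloor must be > 0")
  hot <- abs(binned$changing_rate) >= rateFloor
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= runLength)
  if (!length(ok)) stop("no stimulus found")
  binned$bin_start[starts[ok[1]]]
}
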