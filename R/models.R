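#' Logistic rate of a ST-neuron model at given temperatures
#'
#' `rate(T) = rateLow + (rateHigh - rateLow) / (1 + exp((T - T0) / w))`: a
#' decreasing logistic joining the two activity plateaus, with slope
#' `-(rateHigh - rateLow) / (4 w)` at the turning point T0.
#'
#' @param model a [STNeuronModel-class].
#' @param temp temperatures in degrees C (vectorized).
#' @return firing rates in APs/s.
#' @export
stRate <- function(model, temp) {
  model@rateLow + (model@rateHigh - model@rateLow) /
    (1 + exp((temp - model@midpointTemp) / model@width))
}

#' Per-bin target firing rate of a TT-neuron under a temperature trace
#'
#' Converts a temperature trace into the phenomenological per-bin firing rate
#' of a transient-temperature neuron. The trace is Gauss-smoothed and cut
#' into 1-s bins; per bin with smoothed changing rate r:
#' \itemize{
#'   \item cooling beyond threshold (r < -theta): target nIF =
#'     `100 + gainCool * ln(|r| / theta)`;
#'   \item heating beyond threshold (r > theta): target nIF =
#'     `max(heatFloorNif, 100 - gainHeat * ln(r / theta))`;
#'   \item otherwise the nIF relaxes exponentially toward 100 with time
#'     constant `adaptTau` from its last driven value (adaptation).
#' }
#' The firing rate is `restingRate * nIF / 100`, clamped to zero outside the
#' temperature working range, and never negative.
#'
#' @param model a [TTNeuronModel-class].
#' @param trace a [TemperatureTrace-class] spanning at least 20 s.
#' @param smoothSigma Gaussian smoothing width in seconds applied before
#'   computing per-bin changing rates (default 0.5).
#' @return data.frame with columns `bin_start` (s), `rate` (Hz) and
#'   `target_nif` (percent).
#' @examples
#' p <- buildProtocol(-0.1, 22, plateauHold = 20, preHold = 15, postHold = 10)
#' tr <- generateTemperatureTrace(p, noiseSd = 0)
#' prof <- ttRateProfile(TTNeuronModel(), tr)
#' prof$target_nif[1]      # resting: 100
#' @export
ttRateProfile <- function(model, trace, smoothSigma = 0.5) {
  if (trace@times[length(trace@times)] - trace@times[1] < 20)
    stop("trace must span at least 20 s")
  binned <- binStimulus(gaussSmooth(trace, smoothSigma))
  r <- binned$changing_rate
  theta <- model@thresholdRate
  n <- length(r)
  nif <- numeric(n)
  decay <- exp(-1 / model@adaptTau)    # per 1-s bin
  last <- 100
  for (i in seq_len(n)) {
    if (r[i] < -theta) {
      last <- 100 + model@gainCool * log(-r[i] / theta)
    } else if (r[i] > theta) {
      last <- max(model@heatFloorNif, 100 - model@gainHeat * log(r[i] / theta))
    } else {
      last <- 100 + (last - 100) * decay
    }
    nif[i] <- max(0, last)
  }
  rate <- model@restingRate * nif / 100
  outside <- binned$mean_temp < model@workingTempLow |
    binned$mean_temp > model@workingTempHigh
  rate[outside] <- 0
  data.frame(bin_start = binned$bin_start, rate = rate, target_nif = nif)
}

#' Per-bin target firing rate of a ST-neuron under a temperature trace
#'
#' Evaluates the model logistic at each 1-s bin's mean temperature of the
#' (smoothed) trace.
#'
#' @param model a [STNeuronModel-class].
#' @param trace a [TemperatureTrace-class].
#' @param smoothSigma Gaussian smoothing width in seconds (default 0.5).
#' @return data.frame with columns `bin_start` (s) and `rate` (APs/s).
#' @export
stRateProfile <- function(model, trace, smoothSigma = 0.5) {
  binned <- binStimulus(gaussSmooth(trace, smoothSigma))
  data.frame(bin_start = binned$bin_start,
             rate = stRate(model, binned$mean_temp))
}
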