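#' Create a TemperatureTrace
#'
#' @param times sample times, seconds, strictly increasing.
#' @param temps temperatures, degrees C, same length as `times`.
#' @return a [TemperatureTrace-class].
#' @examples
#' tr <- TemperatureTrace(seq(0, 10, 0.25), rep(25, 41))
#' traceTimes(tr)[1:3]
#' @export
TemperatureTrace <- function(times, temps) {
  new("TemperatureTrace", times = as.numeric(times), temps = as.numeric(temps))
}

#' Create a SpikeTrain
#'
#' @param times sorted, unique spike times in seconds.
#' @return a [SpikeTrain-class].
#' @examples
#' SpikeTrain(c(0.1, 0.2, 0.35))
#' @export
SpikeTrain <- function(times = numeric()) {
  new("SpikeTrain", times = as.numeric(times))
}

#' Create a TT-neuron rate model
#'
#' Defaults describe a typical transient-temperature (flux detector) unit:
#' 40 Hz resting discharge, a cooling gain of 60 nIF percent per decade of
#' stimulus intensity (expressed per ln-unit internally), a response-onset
#' rate of 0.02 degC/s, 30 s adaptation time constant, a 21-38 degC working
#' range, and regular firing (gamma renewal order 4).
#'
#' @param restingRate resting discharge, Hz.
#' @param gainCool cooling gain, nIF percent per ln-unit of cooling rate.
#' @param gainHeat heating suppression gain, nIF percent per ln-unit.
#' @param thresholdRate response-onset changing rate, degC/s.
#' @param adaptTau adaptation time constant, s.
#' @param workingTempLow,workingTempHigh working-range bounds, degC.
#' @param heatFloorNif sustained suppression floor during heating, nIF
#'   percent (default 0 = complete silencing).
#' @param isiShape gamma renewal order (>= 1).
#' @return a [TTNeuronModel-class].
#' @examples
#' TTNeuronModel()                     # defaults
#' TTNeuronModel(gainCool = 100 / log(10))  # 100 %/decade unit
#' @export
TTNeuronModel <- function(restingRate = 40,
                          gainCool = 60 / log(10),
                          gainHeat = 32 / log(10),
                          thresholdRate = 0.02,
                          adaptTau = 30,
                          workingTempLow = 21,
                          workingTempHigh = 38,
                          heatFloorNif = 0,
                          isiShape = 4) {
  new("TTNeuronModel",
      restingRate = restingRate, gainCool = gainCool, gainHeat = gainHeat,
      thresholdRate = thresholdRate, adaptTau = adaptTau,
      workingTempLow = workingTempLow, workingTempHigh = workingTempHigh,
      heatFloorNif = heatFloorNif, isiShape = isiShape)
}

#' Create a ST-neuron rate model
#'
#' Defaults describe a typical steady-temperature unit: activity plateaus of
#' 50 and 29.5 APs/s, turning point at 30 degC, and a logistic width of
#' 0.78846 degC, giving a turning-point sensitivity of -6.5 APs per degC.
#'
#' @param rateHigh low-temperature plateau, APs/s.
#' @param rateLow high-temperature plateau, APs/s.
#' @param midpointTemp turning point T0, degC.
#' @param width logistic scale w, degC.
#' @param isiShape gamma renewal order (>= 1).
#' @return a [STNeuronModel-class].
#' @examples
#' m <- STNeuronModel()
#' stRate(m, 30)   # midpoint: (50 + 29.5) / 2
#' @export
STNeuronModel <- function(rateHigh = 50,
                          rateLow = 29.5,
                          midpointTemp = 30,
                          width = (50 - 29.5) / (4 * 6.5),
                          isiShape = 4) {
  new("STNeuronModel",
      rateHigh = rateHigh, rateLow = rateLow,
      midpointTemp = midpointTemp, width = width, isiShape = isiShape)
}

#' Assemble a Recording
#'
#' @param trace a [TemperatureTrace-class].
#' @param train a [SpikeTrain-class].
#' @param unitId unit identifier.
#' @param neuronClass \code{"TT"}, \code{"ST"} or \code{"unknown"}.
#' @param protocolOnset stimulus onset in seconds when known, else NA.
#' @return a [Recording-class].
#' @export
Recording <- function(trace, train, unitId = "unit1",
                      neuronClass = c("unknown", "TT", "ST"),
                      protocolOnset = NA_real_) {
  neuronClass <- match.arg(neuronClass)
  new("Recording", unitId = as.character(unitId), neuronClass = neuronClass,
      trace = trace, train = train, protocolOnset = as.numeric(protocolOnset))
}

# ---- accessors ------------------------------------------------------------

#' Accessors for traces, spike trains and recordings
#'
#' @param x a [TemperatureTrace-class], [SpikeTrain-class] or
#'   [Recording-class].
#' @return `traceTimes`/`traceTemps`: numeric vectors; `spikeTimes`: numeric
#'   vector of spike times; `nSpikes`: integer; `unitId`/`neuronClass`:
#'   character scalars.
#' @name accessors
NULL

#' @rdname accessors
#' @export
traceTimes <- function(x) {
  if (is(x, "Recording")) x <- x@trace
  x@times
}

#' @rdname accessors
#' @export
traceTemps <- function(x) {
  if (is(x, "Recording")) x <- x@trace
  x@temps
}

#' @rdname accessors
#' @export
spikeTimes <- function(x) {
  if (is(x, "Recording")) x <- x@train
  x@times
}

#' @rdname accessors
#' @export
nSpikes <- function(x) length(spikeTimes(x))

#' @rdname accessors
#' @export
unitId <- function(x) x@unitId

#' @rdname accessors
#' @export
neuronClass <- function(x) x@neuronClass

#' @name fit-accessors
#' @title Accessors for fit results
#' @param x a [TTFitResult-class] or [STFitResult-class].
#' @return numeric or logical scalars (see the individual accessor).
NULL

#' @rdname fit-accessors
#' @export
slopeDecade <- function(x) x@slopeDecade

#' @rdname fit-accessors
#' @export
qcPass <- function(x) x@qcPass

#' @rdname fit-accessors
#' @export
converged <- function(x) x@converged

#' @rdname fit-accessors
#' @export
midpointTemp <- function(x) x@midpointTemp

#' @rdname fit-accessors
#' @export
slopeAtMidpoint <- function(x) x@slopeAtMidpoint

#' @rdname fit-accessors
#' @export
noiseLevel <- function(x) x@noiseLevel

# ---- show methods ---------------------------------------------------------

setMethod("show", "StimulusProtocol", function(object) {
  rampDur <- abs(object@plateauTemp - object@startTemp) / abs(object@rampRate)
  cat(sprintf(
    "StimulusProtocol: %.4g -> %.4g degC at %+.3g degC/s (ramp %.4g s), hold %.4g s\n",
    object@startTemp, object@plateauTemp, object@rampRate, rampDur,
    object@plateauHold))
  cat(sprintf("  preHold %.4g s, postHold %.4g s, sampled at %.4g Hz\n",
              object@preHold, object@postHold, object@sampleRate))
})

setMethod("show", "TemperatureTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("TemperatureTrace: %d samples, %.4g-%.4g s, %.4g-%.4g degC\n",
              n, object@times[1], object@times[n],
              min(object@temps), max(object@temps)))
})

setMethod("show", "SpikeTrain", function(object) {
  n <- length(object@times)
  if (n == 0) cat("SpikeTrain: empty\n")
  else cat(sprintf("SpikeTrain: %d spikes, %.4g-%.4g s\n",
                   n, object@times[1], object@times[n]))
})

setMethod("show", "TTNeuronModel", function(object) {
  cat(sprintf(
    "TTNeuronModel: resting %.4g Hz, gain %.4g (cool) / %.4g (heat) %%/decade\n",
    object@restingRate, object@gainCool * log(10), object@gainHeat * log(10)))
  cat(sprintf(
    "  threshold %.3g degC/s, tau %.4g s, working %.4g-%.4g degC, isiShape %.3g\n",
    object@thresholdRate, object@adaptTau, object@workingTempLow,
    object@workingTempHigh, object@isiShape))
})

setMethod("show", "STNeuronModel", function(object) {
  cat(sprintf(
    "STNeuronModel: plateaus %.4g/%.4g APs/s, T0 %.4g degC, width %.4g degC (slope %.4g APs/degC), isiShape %.3g\n",
    object@rateHigh, object@rateLow, object@midpointTemp, object@width,
    -(object@rateHigh - object@rateLow) / (4 * object@width), object@isiShape))
})

setMethod("show", "BaselineStats", function(object) {
  cat(sprintf(
    "BaselineStats: window %.4g-%.4g s (%d bins), resting %.4g Hz, noise level %.3g%%\n",
    object@windowStart, object@windowEnd, object@nBins, object@meanRateHz,
    object@noiseLevel))
})

setMethod("show", "TTFitResult", function(object) {
  cat(sprintf("TTFitResult (%s): n = %d points\n",
              object@direction, object@nPoints))
  cat(sprintf(
    "  differential sensitivity %.4g %%/decade (slope %.4g %%/ln-unit), intercept %.4g%%\n",
    object@slopeDecade, object@slopeLn, object@intercept))
  cat(sprintf("  Pearson r %.3g, p %.3g, sigma %.3g%% -> QC %s\n",
              object@pearsonR, object@pValue, object@residualSd,
              if (isTRUE(object@qcPass)) "pass" else "FAIL"))
  if (is.finite(object@detectionThreshold))
    cat(sprintf("  detection threshold %+.4g degC/s (%s)\n",
                object@detectionThreshold, object@thresholdFlag))
  if (is.finite(object@resolvingPower))
    cat(sprintf("  resolving power %.3g\n", object@resolvingPower))
})

setMethod("show", "STFitResult", function(object) {
  cat(sprintf(
    "STFitResult: plateaus %.4g/%.4g APs/s, T0 %.4g degC, width %.4g degC\n",
    object@rateHigh, object@rateLow, object@midpointTemp, object@width))
  cat(sprintf("  sensitivity at T0 %.4g APs/degC, converged %s (%d iter, %d bins)\n",
              object@slopeAtMidpoint, object@converged, object@iterations,
              object@nBins))
  if (is.finite(object@workingLow))
    cat(sprintf("  working range %.4g-%.4g degC (%s rule)\n",
                object@workingLow, object@workingHigh, object@workingRule))
  if (is.finite(object@resolvingPowerC))
    cat(sprintf("  resolving power %.3g degC\n", object@resolvingPowerC))
  if (is.finite(object@plateauDropPct))
    cat(sprintf("  activity drop between plateaus %.3g%%\n",
                object@plateauDropPct))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (%s):\n", object@unitId, object@neuronClass))
  show(object@trace)
  show(object@train)
  if (is.finite(object@protocolOnset))
    cat(sprintf("  protocol onset %.4g s\n", object@protocolOnset))
})
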