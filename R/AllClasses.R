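#' @import methods
#' @importFrom stats approx coef convolve cor cor.test dnorm lm median pnorm
#'   pt qnorm rgamma rnorm runif sd var wilcox.test
NULL

#' StimulusProtocol: a ramp-plateau-ramp temperature stimulation protocol
#'
#' The canonical stimulation protocol: hold at a starting temperature, ramp at
#' a constant temperature changing rate to a plateau temperature, hold the
#' plateau (steady state) for a fixed time, ramp back at the same rate with
#' opposite sign, and hold again. The implied waveform is continuous and
#' piecewise linear.
#'
#' @slot startTemp starting (and final) steady-state temperature, degrees C.
#' @slot plateauTemp plateau temperature, degrees C.
#' @slot rampRate signed temperature changing rate of the first ramp, degrees
#'   C per second. The return ramp uses \code{-rampRate}.
#' @slot plateauHold plateau duration, seconds.
#' @slot preHold hold at \code{startTemp} before stimulus onset, seconds.
#' @slot postHold hold at \code{startTemp} after the return ramp, seconds.
#' @slot sampleRate nominal sampling rate of the recorded trace, Hz.
#' @seealso [buildProtocol()], [generateTemperatureTrace()]
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(
    startTemp   = "numeric",
    plateauTemp = "numeric",
    rampRate    = "numeric",
    plateauHold = "numeric",
    preHold     = "numeric",
    postHold    = "numeric",
    sampleRate  = "numeric"
  )
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (length(object@rampRate) != 1L || !is.finite(object@rampRate) ||
      abs(object@rampRate) < 1e-3)
    msg <- c(msg, "abs(rampRate) must be finite and >= 0.001 degC/s")
  if (object@plateauHold < 0) msg <- c(msg, "plateauHold must be >= 0")
  if (object@preHold < 0 || object@postHold < 0)
    msg <- c(msg, "preHold and postHold must be >= 0")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' TemperatureTrace: a sampled temperature record
#'
#' Timestamped temperature samples, nominally at 4 Hz, as recorded by a
#' thermocouple placed at the stimulation site.
#'
#' @slot times sample times in seconds, strictly increasing.
#' @slot temps temperatures in degrees C, same length as \code{times}.
#' @seealso [TemperatureTrace()], [gaussSmooth()], [binStimulus()]
#' @exportClass TemperatureTrace
setClass("TemperatureTrace",
  representation(times = "numeric", temps = "numeric")
)

setValidity("TemperatureTrace", function(object) {
  msg <- character()
  if (length(object@times) < 2L) msg <- c(msg, "need at least 2 samples")
  if (length(object@times) != length(object@temps))
    msg <- c(msg, "times and temps must have equal length")
  if (anyNA(object@times) || anyNA(object@temps))
    msg <- c(msg, "missing values are not allowed")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' SpikeTrain: sorted spike times of one unit
#'
#' Spike (action potential) times of a single sorted unit, in seconds,
#' strictly increasing.
#'
#' @slot times spike times in seconds.
#' @seealso [SpikeTrain()], [instantaneousFrequency()], [binActivity()]
#' @exportClass SpikeTrain
setClass("SpikeTrain", representation(times = "numeric"))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (anyNA(object@times)) msg <- c(msg, "missing spike times are not allowed")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msg <- c(msg, "spike times must be strictly increasing (sorted, unique)")
  if (length(msg)) msg else TRUE
})

#' TTNeuronModel: phenomenological rate model of a transient-temperature neuron
#'
#' Describes the firing-rate response of a cold-sensitive flux detector
#' (TT-neuron): a resting discharge, a phasic log-linear gain to the
#' temperature changing rate during stimulation, exponential adaptation back
#' to the resting level at steady state, and silencing outside a wide
#' temperature working range.
#'
#' @slot restingRate resting discharge, Hz (spikes per second).
#' @slot gainCool response gain to cooling, nIF percentage points per
#'   ln-unit of cooling rate above threshold.
#' @slot gainHeat suppression gain to heating, nIF percentage points per
#'   ln-unit of heating rate above threshold.
#' @slot thresholdRate response-onset temperature changing rate, degrees C/s.
#' @slot adaptTau time constant of the exponential relaxation of the nIF back
#'   to 100 percent at steady state, seconds.
#' @slot workingTempLow,workingTempHigh temperature working range bounds,
#'   degrees C; outside this range the resting discharge ceases.
#' @slot heatFloorNif sustained suppression floor during heating, in nIF
#'   percent (0 = complete silencing; ~20 mimics neurons that keep a reduced
#'   sustained discharge).
#' @slot isiShape gamma renewal order of the interspike-interval
#'   distribution, dimensionless, >= 1 (1 = Poisson).
#' @seealso [TTNeuronModel()], [ttRateProfile()]
#' @exportClass TTNeuronModel
setClass("TTNeuronModel",
  representation(
    restingRate     = "numeric",
    gainCool        = "numeric",
    gainHeat        = "numeric",
    thresholdRate   = "numeric",
    adaptTau        = "numeric",
    workingTempLow  = "numeric",
    workingTempHigh = "numeric",
    heatFloorNif    = "numeric",
    isiShape        = "numeric"
  )
)

setValidity("TTNeuronModel", function(object) {
  msg <- character()
  if (object@restingRate <= 0) msg <- c(msg, "restingRate must be > 0")
  if (object@thresholdRate <= 0) msg <- c(msg, "thresholdRate must be > 0")
  if (object@adaptTau <= 0) msg <- c(msg, "adaptTau must be > 0")
  if (object@workingTempLow >= object@workingTempHigh)
    msg <- c(msg, "workingTempLow must be < workingTempHigh")
  if (object@heatFloorNif < 0) msg <- c(msg, "heatFloorNif must be >= 0")
  if (object@isiShape < 1) msg <- c(msg, "isiShape must be >= 1")
  if (length(msg)) msg else TRUE
})

#' STNeuronModel: logistic rate model of a steady-temperature neuron
#'
#' Describes the sustained firing rate of a cold-sensitive steady-temperature
#' detector (ST-neuron): two activity plateaus joined by a decreasing
#' logistic centred at the turning-point temperature.
#'
#' @slot rateHigh low-temperature activity plateau, APs/s.
#' @slot rateLow high-temperature activity plateau, APs/s.
#' @slot midpointTemp turning-point temperature T0, degrees C.
#' @slot width logistic scale w, degrees C; the slope at the turning point is
#'   \code{-(rateHigh - rateLow) / (4 * width)}.
#' @slot isiShape gamma renewal order of the interspike intervals, >= 1.
#' @seealso [STNeuronModel()], [stRateProfile()]
#' @exportClass STNeuronModel
setClass("STNeuronModel",
  representation(
    rateHigh     = "numeric",
    rateLow      = "numeric",
    midpointTemp = "numeric",
    width        = "numeric",
    isiShape     = "numeric"
  )
)

setValidity("STNeuronModel", function(object) {
  msg <- character()
  if (!(object@rateHigh > object@rateLow)) msg <- c(msg, "rateHigh must be > rateLow")
  if (object@rateLow < 0) msg <- c(msg, "rateLow must be >= 0")
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (object@isiShape < 1) msg <- c(msg, "isiShape must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BaselineStats: resting-activity statistics of one recording
#'
#' Summary of the pre-stimulus baseline window used to normalize the
#' instantaneous frequency: the mean of the per-bin median IF defines nIF =
#' 100 percent, and twice the standard deviation of the baseline nIF is the
#' noise level.
#'
#' @slot windowStart,windowEnd baseline window, seconds.
#' @slot meanNif mean baseline nIF, percent (100 by construction).
#' @slot sdNif standard deviation of the baseline nIF, percent.
#' @slot noiseLevel noise level, percent; exactly \code{2 * sdNif}.
#' @slot meanRateHz raw resting activity (mean of the per-bin median IF over
#'   the baseline window), Hz.
#' @slot nBins number of baseline bins with a defined median IF.
#' @seealso [normalizeNif()]
#' @exportClass BaselineStats
setClass("BaselineStats",
  representation(
    windowStart = "numeric",
    windowEnd   = "numeric",
    meanNif     = "numeric",
    sdNif       = "numeric",
    noiseLevel  = "numeric",
    meanRateHz  = "numeric",
    nBins       = "integer"
  )
)

setValidity("BaselineStats", function(object) {
  if (!isTRUE(all.equal(object@noiseLevel, 2 * object@sdNif)))
    "noiseLevel must equal 2 * sdNif" else TRUE
})

#' TTFitResult: log-linear dose-response characterization of a TT-neuron
#'
#' Result of the Weber-Fechner analysis: ordinary least squares of nIF on the
#' natural log of the absolute temperature changing rate, with quality
#' control, detection threshold, differential sensitivity and resolving
#' power.
#'
#' @slot direction \code{"cooling"} or \code{"heating"}.
#' @slot slopeLn regression slope b, nIF percent per ln-unit of stimulus.
#' @slot slopeDecade differential sensitivity, nIF percent per decade of
#'   stimulus intensity; exactly \code{slopeLn * log(10)}.
#' @slot intercept regression intercept, nIF percent at ln|rate| = 0.
#' @slot pearsonR Pearson correlation between ln|rate| and nIF.
#' @slot pValue two-sided p-value of the regression slope (t distribution).
#' @slot residualSd residual standard deviation sigma of the nIF about the
#'   regression, percent, with an n - 1 divisor.
#' @slot stimNoiseLevel noise level during stimulation, percent; exactly
#'   \code{2 * residualSd}.
#' @slot baselineNoise resting-activity noise level used for the detection
#'   threshold, percent.
#' @slot nPoints number of dose-response points.
#' @slot qcPass TRUE when \code{pValue < 0.05} and the Pearson correlation is
#'   above 0.3 (cooling) or below -0.3 (heating).
#' @slot detectionThreshold smallest temperature changing rate whose fitted
#'   response exceeds the resting noise level, degrees C/s, signed by
#'   direction (NA until computed).
#' @slot thresholdFlag \code{"fit"} when the threshold is the regression/noise
#'   crossing, \code{"below-smallest-tested"} when the crossing lies below the
#'   smallest applied stimulus.
#' @slot resolvingPower dimensionless resolving power Delta-x (NA until
#'   computed).
#' @seealso [fitDoseResponse()], [detectionThreshold()], [resolvingPower()]
#' @exportClass TTFitResult
setClass("TTFitResult",
  representation(
    direction          = "character",
    slopeLn            = "numeric",
    slopeDecade        = "numeric",
    intercept          = "numeric",
    pearsonR           = "numeric",
    pValue             = "numeric",
    residualSd         = "numeric",
    stimNoiseLevel     = "numeric",
    baselineNoise      = "numeric",
    nPoints            = "integer",
    qcPass             = "logical",
    detectionThreshold = "numeric",
    thresholdFlag      = "character",
    resolvingPower     = "numeric"
  )
)

setValidity("TTFitResult", function(object) {
  msg <- character()
  if (!object@direction %in% c("cooling", "heating"))
    msg <- c(msg, "direction must be 'cooling' or 'heating'")
  if (!isTRUE(all.equal(object@slopeDecade, object@slopeLn * log(10))))
    msg <- c(msg, "slopeDecade must equal slopeLn * log(10)")
  if (is.finite(object@resolvingPower) && object@resolvingPower < 0)
    msg <- c(msg, "resolvingPower must be >= 0")
  if (length(msg)) msg else TRUE
})

#' STFitResult: sigmoidal characterization of a ST-neuron
#'
#' Result of fitting a decreasing four-parameter logistic to the mean firing
#' rate versus temperature, with the working range (10 percent departure
#' rule), turning-point sensitivity, linearized resolving power in degrees C,
#' and the two activity plateaus.
#'
#' @slot rateHigh,rateLow fitted activity plateaus, APs/s.
#' @slot midpointTemp fitted turning point T0, degrees C.
#' @slot width fitted logistic scale w, degrees C.
#' @slot slopeAtMidpoint sensitivity at the turning point, APs per degree C;
#'   \code{-(rateHigh - rateLow) / (4 * width)} in closed form.
#' @slot workingLow,workingHigh temperature working range, degrees C (NA
#'   until computed).
#' @slot workingRule the working-range rule used, \code{"literal"} or
#'   \code{"span"} (empty until computed).
#' @slot resolvingPowerC resolving power for steady-state temperature,
#'   degrees C (NA until computed).
#' @slot plateauLowTempRate,plateauHighTempRate observed mean rate below
#'   workingLow and above workingHigh, APs/s (NA until computed).
#' @slot plateauDropPct relative difference between the two activity levels,
#'   percent (NA until computed).
#' @slot converged TRUE when the Gauss-Newton iteration met its tolerance.
#' @slot iterations number of Gauss-Newton iterations used.
#' @slot nBins number of (temperature, rate) bins fitted.
#' @seealso [fitSigmoid()], [workingRange()], [stResolvingPower()]
#' @exportClass STFitResult
setClass("STFitResult",
  representation(
    rateHigh            = "numeric",
    rateLow             = "numeric",
    midpointTemp        = "numeric",
    width               = "numeric",
    slopeAtMidpoint     = "numeric",
    workingLow          = "numeric",
    workingHigh         = "numeric",
    workingRule         = "character",
    resolvingPowerC     = "numeric",
    plateauLowTempRate  = "numeric",
    plateauHighTempRate = "numeric",
    plateauDropPct      = "numeric",
    converged           = "logical",
    iterations          = "integer",
    nBins               = "integer"
  )
)

setValidity("STFitResult", function(object) {
  msg <- character()
  if (!(object@rateHigh > object@rateLow))
    msg <- c(msg, "rateHigh must be > rateLow")
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  expected <- -(object@rateHigh - object@rateLow) / (4 * object@width)
  if (!isTRUE(all.equal(object@slopeAtMidpoint, expected, tolerance = 1e-6)))
    msg <- c(msg, "slopeAtMidpoint must equal -(rateHigh-rateLow)/(4*width)")
  if (is.finite(object@workingLow) && is.finite(object@workingHigh) &&
      !(object@workingLow < object@midpointTemp &&
        object@midpointTemp < object@workingHigh))
    msg <- c(msg, "workingLow < midpointTemp < workingHigh must hold")
  if (is.finite(object@resolvingPowerC) && object@resolvingPowerC < 0)
    msg <- c(msg, "resolvingPowerC must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Recording: one paired temperature trace and spike train
#'
#' A per-unit recording: the stimulus record (temperature trace), the
#' response record (sorted spike train), the neuron class and, when the
#' stimulation controller provides it, the protocol onset time.
#'
#' @slot unitId unit identifier, unique within a cohort.
#' @slot neuronClass \code{"TT"}, \code{"ST"} or \code{"unknown"}.
#' @slot trace a [TemperatureTrace-class].
#' @slot train a [SpikeTrain-class].
#' @slot protocolOnset stimulus onset in seconds when known from the
#'   protocol, otherwise NA (onset is then detected from the trace).
#' @seealso [readRecording()], [runRecording()]
#' @exportClass Recording
setClass("Recording",
  representation(
    unitId        = "character",
    neuronClass   = "character",
    trace         = "TemperatureTrace",
    train         = "SpikeTrain",
    protocolOnset = "numeric"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (!object@neuronClass %in% c("TT", "ST", "unknown"))
    msg <- c(msg, "neuronClass must be 'TT', 'ST' or 'unknown'")
  tr <- object@trace@times
  sp <- object@train@times
  if (length(sp)) {
    dt <- stats::median(diff(tr))
    if (min(sp) < tr[1] - dt || max(sp) > tr[length(tr)] + dt)
      msg <- c(msg, "spike times must lie within the trace time span")
  }
  if (length(msg)) msg else TRUE
})
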