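#' Simulate a spike train from a per-bin rate profile
#'
#' Generates spike times by an inhomogeneous gamma-renewal process of order
#' `isiShape` via time rescaling: unit-mean gamma interarrivals (shape
#' `isiShape`, rate `isiShape`) are laid out in rescaled time and mapped back
#' through the inverse of the cumulative rate. `isiShape = 1` reduces to an
#' inhomogeneous Poisson process; larger orders give more regular discharge
#' (ISI coefficient of variation `1 / sqrt(isiShape)`). The expected spike
#' count equals the integral of the rate profile.
#'
#' @param rateProfile data.frame with columns `bin_start` (s, contiguous 1-s
#'   bins) and `rate` (Hz, >= 0), e.g. from [ttRateProfile()].
#' @param isiShape gamma renewal order (>= 1).
#' @param seed optional integer for reproducibility.
#' @return a [SpikeTrain-class].
#' @examples
#' prof <- data.frame(bin_start = 0:99, rate = 50)
#' nSpikes(simulateSpikes(prof, isiShape = 1, seed = 1))  # ~5000
#' @export
simulateSpikes <- function(rateProfile, isiShape = 4, seed = NULL) {
  rates <- rateProfile$rate
  if (any(rates < 0)) stop("negative rate")
  if (isiShape < 1) stop("isiShape must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Lam <- c(0, cumsum(rates))                 # rescaled time at bin edges
  total <- Lam[length(Lam)]
  if (total <= 0) return(SpikeTrain())
  n <- ceiling(total + 10 * sqrt(total) + 50)
  s <- cumsum(rgamma(n, shape = isiShape, rate = isiShape))
  while (s[length(s)] < total) {             # top up in the unlikely shortfall
    extra <- cumsum(rgamma(n, shape = isiShape, rate = isiShape))
    s <- c(s, s[length(s)] + extra)
  }
  s <- s[s < total]
  if (!length(s)) return(SpikeTrain())
  idx <- findInterval(s, Lam, rightmost.closed = TRUE)
  # findInterval returns the last edge <= s, so zero-rate bins (repeated
  # cumulative values) are never selected for s strictly inside the span
  frac <- (s - Lam[idx]) / rates[idx]
  SpikeTrain(rateProfile$bin_start[idx] + frac)
}

#' Simulate one TT-neuron recording
#'
#' Generates a noisy temperature trace from the protocol, drives the
#' TT-neuron rate model with it, and draws a gamma-renewal spike train.
#'
#' @param model a [TTNeuronModel-class].
#' @param protocol a [StimulusProtocol-class].
#' @param noiseSd temperature measurement noise, degC.
#' @param seed optional integer; controls trace and spikes.
#' @param unitId unit identifier.
#' @return a [Recording-class] with `protocolOnset` set to the protocol's
#'   pre-hold time; the ground-truth model and protocol are attached as the
#'   attribute `"truth"`.
#' @export
simulateTTRecording <- function(model, protocol, noiseSd = 0.01, seed = NULL,
                                unitId = "tt1") {
  if (!is.null(seed)) set.seed(seed)
  trace <- generateTemperatureTrace(protocol, noiseSd = noiseSd)
  prof <- ttRateProfile(model, trace)
  train <- simulateSpikes(prof, isiShape = model@isiShape)
  rec <- Recording(trace, train, unitId = unitId, neuronClass = "TT",
                   protocolOnset = protocol@preHold)
  attr(rec, "truth") <- list(model = model, protocol = protocol)
  rec
}

#' Simulate one ST-neuron recording
#'
#' @param model a [STNeuronModel-class].
#' @param protocol a [StimulusProtocol-class]; for ST analysis use a slow
#'   ramp (e.g. +0.01 degC/s).
#' @param noiseSd temperature measurement noise, degC.
#' @param seed optional integer.
#' @param unitId unit identifier.
#' @return a [Recording-class] with the ground truth attached as attribute
#'   `"truth"`.
#' @export
simulateSTRecording <- function(model, protocol, noiseSd = 0.01, seed = NULL,
                                unitId = "st1") {
  if (!is.null(seed)) set.seed(seed)
  trace <- generateTemperatureTrace(protocol, noiseSd = noiseSd)
  prof <- stRateProfile(model, trace)
  train <- simulateSpikes(prof, isiShape = model@isiShape)
  rec <- Recording(trace, train, unitId = unitId, neuronClass = "ST",
                   protocolOnset = protocol@preHold)
  attr(rec, "truth") <- list(model = model, protocol = protocol)
  rec
}

#' Write a recording to CSV files with a ground-truth sidecar
#'
#' Writes `<prefix>_temperature.csv` (columns `time_s`, `temp_c`),
#' `<prefix>_spikes.csv` (column `spike_time_s`) and, when the recording
#' carries simulation ground truth, `<prefix>_truth.json` with the model and
#' protocol parameters.
#'
#' @param rec a [Recording-class].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix (default the unit id).
#' @return invisibly, the paths written.
#' @export
writeRecording <- function(rec, dir, prefix = unitId(rec)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tempPath <- file.path(dir, paste0(prefix, "_temperature.csv"))
  spikePath <- file.path(dir, paste0(prefix, "_spikes.csv"))
  utils::write.csv(
    data.frame(time_s = traceTimes(rec), temp_c = traceTemps(rec)),
    tempPath, row.names = FALSE)
  utils::write.csv(
    data.frame(spike_time_s = spikeTimes(rec)),
    spikePath, row.names = FALSE)
  paths <- c(tempPath, spikePath)
  truth <- attr(rec, "truth")
  if (!is.null(truth)) {
    truthPath <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(
      list(unit_id = unitId(rec), neuron_class = neuronClass(rec),
           model = s4ToList(truth$model), protocol = s4ToList(truth$protocol)),
      truthPath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truthPath)
  }
  invisible(paths)
}

# flatten an S4 object's slots into a named list (for JSON sidecars)
s4ToList <- function(object) {
  nm <- slotNames(class(object))
  stats::setNames(lapply(nm, function(s) slot(object, s)), nm)
}

#' Simulate a cohort of TT-neuron recordings
#'
#' Each unit is stimulated once per ramp rate with the canonical
#' ramp-plateau-ramp protocol; the per-unit seed stream is derived from
#' `seed`.
#'
#' @param nUnits number of units (default 20).
#' @param model a [TTNeuronModel-class] shared by all units.
#' @param rampRates signed ramp rates, degC/s (default cooling at
#'   -0.03, -0.1, -0.3).
#' @param plateauTemp plateau temperature, degC (default 22: a 3 degC cold
#'   stimulus from the 25 degC start).
#' @param plateauHold plateau duration, s (default 500).
#' @param startTemp starting temperature, degC.
#' @param noiseSd temperature noise, degC.
#' @param seed integer master seed.
#' @return list of units; each unit is a list of [Recording-class] objects,
#'   one per ramp rate.
#' @export
simulateTTCohort <- function(nUnits = 20, model = TTNeuronModel(),
                             rampRates = c(-0.03, -0.1, -0.3),
                             plateauTemp = 22, plateauHold = 500,
                             startTemp = 25, noiseSd = 0.01, seed = 1) {
  lapply(seq_len(nUnits), function(u) {
    lapply(seq_along(rampRates), function(k) {
      p <- buildProtocol(rampRates[k], plateauTemp,
                         plateauHold = plateauHold, startTemp = startTemp)
      simulateTTRecording(model, p, noiseSd = noiseSd,
                          seed = seed + 1000L * u + k,
                          unitId = sprintf("tt%02d", u))
    })
  })
}

#' Simulate a cohort of ST-neuron recordings
#'
#' Each unit receives one slow warming ramp covering the neuron's working
#' range (default +0.01 degC/s from 23 to 37 degC).
#'
#' @param nUnits number of units (default 7).
#' @param model a [STNeuronModel-class] shared by all units.
#' @param rampRate signed ramp rate, degC/s.
#' @param startTemp,plateauTemp ramp start and end temperatures, degC.
#' @param plateauHold plateau duration, s.
#' @param noiseSd temperature noise, degC.
#' @param seed integer master seed.
#' @return list of [Recording-class] objects, one per unit.
#' @export
simulateSTCohort <- function(nUnits = 7, model = STNeuronModel(),
                             rampRate = 0.01, startTemp = 23,
                             plateauTemp = 37, plateauHold = 500,
                             noiseSd = 0.01, seed = 1) {
  lapply(seq_len(nUnits), function(u) {
    p <- buildProtocol(rampRate, plateauTemp, plateauHold = plateauHold,
                       startTemp = startTemp)
    simulateSTRecording(model, p, noiseSd = noiseSd, seed = seed + 100L * u,
                        unitId = sprintf("st%02d", u))
  })
}
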