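#' Build a ramp-plateau-ramp stimulation protocol
#'
#' Constructs the canonical stimulation protocol: hold at `startTemp` for
#' `preHold` seconds, ramp to `plateauTemp` at `rampRate`, hold the plateau
#' (steady state) for `plateauHold` seconds, ramp back at `-rampRate`, then
#' hold for `postHold` seconds. The two transition phases use the same
#' changing rate with opposite arithmetic signs.
#'
#' @param rampRate signed temperature changing rate, degC/s. Must have the
#'   same sign as `plateauTemp - startTemp`.
#' @param plateauTemp plateau temperature, degC.
#' @param plateauHold plateau duration, s (default 500).
#' @param startTemp starting steady-state temperature, degC (default 25).
#' @param sampleRate trace sampling rate, Hz (default 4).
#' @param preHold,postHold hold times around the stimulus, s.
#' @return a [StimulusProtocol-class].
#' @examples
#' p <- buildProtocol(-0.1, 20)   # 50 s ramp down, 500 s hold, 50 s ramp up
#' protocolRampDuration(p)
#' @export
buildProtocol <- function(rampRate, plateauTemp, plateauHold = 500,
                          startTemp = 25, sampleRate = 4,
                          preHold = 30, postHold = 30) {
  if (!is.finite(rampRate) || rampRate == 0)
    stop("rampRate must be nonzero")
  dT <- plateauTemp - startTemp
  if (sign(dT) != sign(rampRate))
    stop("sign mismatch: rampRate and (plateauTemp - startTemp) must have the same sign")
  new("StimulusProtocol",
      startTemp = startTemp, plateauTemp = plateauTemp, rampRate = rampRate,
      plateauHold = plateauHold, preHold = preHold, postHold = postHold,
      sampleRate = sampleRate)
}

#' Duration of one transition ramp of a protocol
#'
#' @param protocol a [StimulusProtocol-class].
#' @return ramp duration in seconds.
#' @export
protocolRampDuration <- function(protocol) {
  abs(protocol@plateauTemp - protocol@startTemp) / abs(protocol@rampRate)
}

#' Total duration of a protocol
#'
#' @param protocol a [StimulusProtocol-class].
#' @return total waveform duration in seconds.
#' @export
protocolDuration <- function(protocol) {
  protocol@preHold + 2 * protocolRampDuration(protocol) +
    protocol@plateauHold + protocol@postHold
}

#' Evaluate the noiseless protocol waveform
#'
#' Piecewise-linear temperature at arbitrary times: pre-hold, down/up ramp,
#' plateau, return ramp, post-hold. Stimulus onset is at `t = preHold`.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param t times in seconds (vectorized).
#' @return temperatures in degrees C.
#' @export
protocolTemperature <- function(protocol, t) {
  rampDur <- protocolRampDuration(protocol)
  t1 <- protocol@preHold              # onset of first ramp
  t2 <- t1 + rampDur                  # plateau start
  t3 <- t2 + protocol@plateauHold     # return ramp start
  t4 <- t3 + rampDur                  # back at startTemp
  temp <- rep(protocol@startTemp, length(t))
  i <- t > t1 & t <= t2
  temp[i] <- protocol@startTemp + protocol@rampRate * (t[i] - t1)
  i <- t > t2 & t <= t3
  temp[i] <- protocol@plateauTemp
  i <- t > t3 & t <= t4
  temp[i] <- protocol@plateauTemp - protocol@rampRate * (t[i] - t3)
  temp
}

#' Sample a temperature trace from a protocol
#'
#' Samples the piecewise-linear protocol waveform at the protocol's sampling
#' rate and adds independent zero-mean Gaussian measurement noise. The
#' default noise (0.01 degC) matches the accuracy of a thermocouple read out
#' in high-resolution mode.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param noiseSd standard deviation of the per-sample measurement noise,
#'   degC (>= 0).
#' @param seed optional integer; identical seeds give identical traces.
#' @return a [TemperatureTrace-class].
#' @examples
#' p <- buildProtocol(-0.1, 24, plateauHold = 10, preHold = 5, postHold = 5)
#' tr <- generateTemperatureTrace(p, noiseSd = 0)
#' range(traceTemps(tr))
#' @export
generateTemperatureTrace <- function(protocol, noiseSd = 0.01, seed = NULL) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / protocol@sampleRate
  times <- seq(0, protocolDuration(protocol), by = dt)
  temps <- protocolTemperature(protocol, times)
  if (noiseSd > 0) temps <- temps + rnorm(length(temps), 0, noiseSd)
  TemperatureTrace(times, temps)
}
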