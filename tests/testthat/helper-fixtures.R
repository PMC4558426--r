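# in-code fixtures shared across test files

# noiseless linear ramp trace: temp = start + rate * t, sampled at `hz`
rampTrace <- function(rate, duration, start = 25, hz = 4) {
  tt <- seq(0, duration, by = 1 / hz)
  TemperatureTrace(tt, start + rate * tt)
}

constantTrace <- function(temp = 25, duration = 30, hz = 4) {
  tt <- seq(0, duration, by = 1 / hz)
  TemperatureTrace(tt, rep(temp, length(tt)))
}

# points exactly on nif = 100 + slopeLn * ln(|rate| / theta)
exactLinePoints <- function(rates, slopeLn = 60 / log(10), theta = 0.01,
                            direction = "cooling") {
  data.frame(log_rate = log(abs(rates)),
             nif = 100 + slopeLn * log(abs(rates) / theta),
             direction = direction, stringsAsFactors = FALSE)
}

# deterministic regular spike train at a fixed rate
regularTrain <- function(rate, duration, t0 = 0) {
  SpikeTrain(seq(t0 + 1 / rate / 2, t0 + duration, by = 1 / rate))
}
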