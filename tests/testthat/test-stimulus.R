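test_that("Gaussian smoothing preserves constants, affine ramps and range", {
  const <- constantTrace(25, 30)
  expect_equal(traceTemps(gaussSmooth(const, 2)), traceTemps(const))

  ramp <- rampTrace(-0.1, 60)
  expect_identical(gaussSmooth(ramp, 0), ramp)          # sigma 0 = identity
  sm <- gaussSmooth(ramp, 0.5)
  interior <- seq_along(traceTimes(ramp)) > 16 &
    seq_along(traceTimes(ramp)) < length(traceTimes(ramp)) - 16
  expect_equal(traceTemps(sm)[interior], traceTemps(ramp)[interior],
               tolerance = 1e-9)

  # never widens the data range (convex weights), even on noisy input
  set.seed(3)
  noisy <- TemperatureTrace(traceTimes(ramp),
                            traceTemps(ramp) + rnorm(length(traceTimes(ramp)),
                                                     0, 0.05))
  out <- traceTemps(gaussSmooth(noisy, 1))
  expect_gte(min(out), min(traceTemps(noisy)))
  expect_lte(max(out), max(traceTemps(noisy)))
  expect_error(gaussSmooth(ramp, -1), "sigma")
})

test_that("stimulus binning is exact on ramps and constants", {
  b <- binStimulus(rampTrace(-0.1, 20))
  expect_equal(b$changing_rate, rep(-0.1, nrow(b)), tolerance = 1e-9)
  # first bin mean of samples 25, 24.975, 24.95, 24.925
  expect_equal(b$mean_temp[1], 24.9625)

  bc <- binStimulus(constantTrace(25, 10))
  expect_true(all(bc$changing_rate == 0))
  expect_true(all(bc$mean_temp == 25))
  expect_error(binStimulus(constantTrace(25, 1.5)), "too short")
})

test_that("binning is translation-covariant over integer shifts", {
  tr <- rampTrace(-0.05, 30)
  shifted <- TemperatureTrace(traceTimes(tr) + 7, traceTemps(tr))
  b1 <- binStimulus(tr)
  b2 <- binStimulus(shifted)
  expect_equal(b2$bin_start, b1$bin_start + 7)
  expect_equal(b2$mean_temp, b1$mean_temp)
  expect_equal(b2$changing_rate, b1$changing_rate)
})

test_that("onset detection finds ramp starts and rejects constant traces", {
  tt <- seq(0, 160, 0.25)
  temps <- ifelse(tt < 100, 25, 25 - 0.1 * (tt - 100))
  onset <- detectOnset(binStimulus(TemperatureTrace(tt, temps)),
                       rateFloor = 0.02)
  expect_lte(abs(onset - 100), 1)
  expect_error(detectOnset(binStimulus(constantTrace(25, 30)),
                           rateFloor = 0.02), "no stimulus found")
  expect_error(detectOnset(binStimulus(constantTrace(25, 30)),
                           rateFloor = 0), "rateFloor")
})

test_that("onset detection tolerates measurement noise on slow ramps", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    tt <- seq(0, 120, 0.25)
    temps <- ifelse(tt < 60, 25, 25 - 0.05 * (tt - 60)) +
      rnorm(length(tt), 0, 0.01)
    sm <- gaussSmooth(TemperatureTrace(tt, temps), 0.5)
    detectOnset(binStimulus(sm), rateFloor = 0.02)
  }, numeric(1))
  expect_true(all(abs(hits - 60) <= 2))
})
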