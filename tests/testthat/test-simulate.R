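test_that("spike simulation honors the integrated rate", {
  # zero rate: no spikes
  expect_equal(nSpikes(simulateSpikes(data.frame(bin_start = 0:9, rate = 0),
                                      seed = 1)), 0)
  # Poisson counts: 100 s at 50 Hz stays within 3 sqrt(5000) of 5000 for
  # nearly all seeds
  prof <- data.frame(bin_start = 0:99, rate = 50)
  counts <- vapply(1:20, function(s)
    nSpikes(simulateSpikes(prof, isiShape = 1, seed = s)), numeric(1))
  expect_gte(sum(abs(counts - 5000) <= 3 * sqrt(5000)), 19)
  # count conservation at 1e4 expected spikes, 5% tolerance
  big <- data.frame(bin_start = 0:199, rate = 50)
  expect_equal(nSpikes(simulateSpikes(big, isiShape = 4, seed = 7)),
               1e4, tolerance = 0.05)
})

test_that("gamma renewal order sets the ISI regularity", {
  prof <- data.frame(bin_start = 0:199, rate = 50)
  isi <- diff(spikeTimes(simulateSpikes(prof, isiShape = 4, seed = 2)))
  expect_gt(length(isi), 5000)
  expect_equal(sd(isi) / mean(isi), 0.5, tolerance = 0.1)  # CV = 1/sqrt(4)
  expect_error(simulateSpikes(prof, isiShape = 0.5), "isiShape")
  expect_error(simulateSpikes(data.frame(bin_start = 0, rate = -1)),
               "negative rate")
})

test_that("spikes land only where the rate is positive", {
  prof <- data.frame(bin_start = 0:29, rate = rep(c(40, 0, 40), each = 10))
  sp <- spikeTimes(simulateSpikes(prof, isiShape = 4, seed = 3))
  expect_false(any(sp > 10.0 & sp < 20.0))
  expect_true(any(sp < 10) && any(sp > 20))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- buildProtocol(-0.1, 22, plateauHold = 60, preHold = 20, postHold = 10)
  r1 <- simulateTTRecording(TTNeuronModel(), p, seed = 99)
  r2 <- simulateTTRecording(TTNeuronModel(), p, seed = 99)
  expect_identical(traceTemps(r1), traceTemps(r2))
  expect_identical(spikeTimes(r1), spikeTimes(r2))
  r3 <- simulateTTRecording(TTNeuronModel(), p, seed = 100)
  expect_false(identical(spikeTimes(r1), spikeTimes(r3)))
})

test_that("recordings round-trip through CSV with ground-truth sidecar", {
  dir <- withr::local_tempdir()
  p <- buildProtocol(-0.1, 23, plateauHold = 30, preHold = 15, postHold = 10)
  rec <- simulateTTRecording(TTNeuronModel(), p, seed = 4, unitId = "u1")
  paths <- writeRecording(rec, dir)
  expect_true(all(file.exists(paths)))
  back <- readRecording(file.path(dir, "u1_temperature.csv"),
                        file.path(dir, "u1_spikes.csv"), unitId = "u1",
                        neuronClass = "TT")
  expect_equal(traceTimes(back), traceTimes(rec))
  expect_equal(traceTemps(back), traceTemps(rec))
  expect_equal(spikeTimes(back), spikeTimes(rec))
  truth <- jsonlite::read_json(file.path(dir, "u1_truth.json"))
  expect_equal(truth$model$restingRate, 40)
  expect_equal(truth$protocol$rampRate, -0.1)
})
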