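test_that("instantaneous frequency is the reciprocal ISI at the second spike", {
  iff <- instantaneousFrequency(SpikeTrain(c(0, 0.1, 0.2, 0.3)))
  expect_equal(iff$if_hz, c(10, 10, 10))
  expect_equal(iff$time, c(0.1, 0.2, 0.3))
  expect_equal(instantaneousFrequency(SpikeTrain(c(0, 0.5, 0.75)))$if_hz,
               c(2, 4))
  expect_equal(nrow(instantaneousFrequency(SpikeTrain(1.5))), 0)
  expect_error(new("SpikeTrain", times = c(1, 1, 2)), "strictly increasing")
})

test_that("activity binning yields median IF and mean rate per 1-s window", {
  bins <- data.frame(bin_start = 0:4)
  act <- binActivity(SpikeTrain(seq(0.05, 0.95, 0.1)), bins)
  expect_equal(act$median_if[1], 10)
  expect_equal(act$mean_rate[1], 10)
  # empty bins: rate 0, median IF missing
  expect_equal(act$mean_rate[3], 0)
  expect_true(is.na(act$median_if[3]))
  # median of IFs {2, 4, 10}: spikes at .1, .6, .85, .95 give ISIs .5 .25 .1
  act2 <- binActivity(SpikeTrain(c(0.1, 0.6, 0.85, 0.95)),
                      data.frame(bin_start = 0))
  expect_equal(act2$median_if, 4)
})

test_that("binned mean rates conserve the total spike count", {
  set.seed(8)
  sp <- sort(runif(500, 0, 50))
  sp <- sp[c(TRUE, diff(sp) > 0)]
  act <- binActivity(SpikeTrain(sp), data.frame(bin_start = 0:49))
  expect_equal(sum(act$mean_rate), sum(sp >= 0 & sp < 50))
})

test_that("nIF normalization fixes the baseline at 100% and 2 SD noise", {
  train <- regularTrain(40, 20)
  act <- binActivity(train, data.frame(bin_start = 0:19))
  res <- normalizeNif(act, onset = 10)
  base <- res$activity$nif[res$activity$bin_start < 10]
  expect_equal(mean(base), 100)
  expect_equal(res$baseline@noiseLevel, 2 * res$baseline@sdNif)
  expect_equal(res$baseline@meanRateHz, 40)

  # a bin at 1.5x the baseline rate maps to nIF 150
  sp <- c(spikeTimes(regularTrain(40, 10)), spikeTimes(regularTrain(60, 1, 10)))
  act2 <- binActivity(SpikeTrain(sp), data.frame(bin_start = 0:10))
  res2 <- normalizeNif(act2, onset = 10)
  expect_equal(res2$activity$nif[11], 150, tolerance = 1e-6)
})

test_that("nIF is invariant to a global time rescaling of firing", {
  act1 <- binActivity(regularTrain(30, 20), data.frame(bin_start = 0:19))
  act2 <- binActivity(regularTrain(60, 20), data.frame(bin_start = 0:19))
  n1 <- normalizeNif(act1, 10)$activity$nif
  n2 <- normalizeNif(act2, 10)$activity$nif
  expect_equal(n1, n2)
})

test_that("recordings with too sparse a baseline are rejected", {
  act <- binActivity(regularTrain(0.4, 20), data.frame(bin_start = 0:19))
  expect_error(normalizeNif(act, onset = 10), "insufficient baseline")
})
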