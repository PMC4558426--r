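test_that("Gauss-Newton recovers a noiseless logistic to high precision", {
  m <- STNeuronModel(rateHigh = 50, rateLow = 29.5, midpointTemp = 30,
                     width = 0.7885)
  temps <- seq(23, 37, 0.1)
  fit <- fitSigmoid(temps, stRate(m, temps))
  expect_true(fit@converged)
  expect_equal(fit@rateHigh, 50, tolerance = 1e-6)
  expect_equal(fit@rateLow, 29.5, tolerance = 1e-6)
  expect_equal(fit@midpointTemp, 30, tolerance = 1e-6)
  expect_equal(fit@width, 0.7885, tolerance = 1e-5)
  expect_equal(fit@slopeAtMidpoint, -20.5 / (4 * 0.7885), tolerance = 1e-6)
  expect_equal(fit@slopeAtMidpoint, -6.5, tolerance = 1e-3)
})

test_that("sigmoid fitting agrees with an independent nls fit on noisy data", {
  set.seed(12)
  m <- STNeuronModel()
  temps <- seq(23, 37, 0.05)
  rates <- stRate(m, temps) + rnorm(length(temps), 0, 2)
  fit <- fitSigmoid(temps, rates)
  ref <- nls(rates ~ rl + (rh - rl) / (1 + exp((temps - T0) / w)),
             start = list(rl = 25, rh = 55, T0 = 29, w = 1))
  rc <- coef(ref)
  expect_equal(fit@rateLow, unname(rc["rl"]), tolerance = 1e-4)
  expect_equal(fit@rateHigh, unname(rc["rh"]), tolerance = 1e-4)
  expect_equal(fit@midpointTemp, unname(rc["T0"]), tolerance = 1e-4)
  expect_equal(fit@width, unname(rc["w"]), tolerance = 1e-3)
})

test_that("sigmoid fitting rejects degenerate inputs", {
  expect_error(fitSigmoid(seq(29, 31, 0.5), rnorm(5, 40)), "12 bins")
  expect_error(fitSigmoid(seq(29, 31, 0.1), rnorm(21, 40, 0.1)),
               "degenerate span")
  set.seed(5)
  temps <- seq(23, 37, 0.5)
  expect_error(fitSigmoid(temps, 30 + 1.5 * (temps - 23) + rnorm(29, 0, 0.5)),
               "do not decrease")
})

test_that("working range inverts the fitted logistic under both rules", {
  m <- STNeuronModel(rateHigh = 50, rateLow = 30, midpointTemp = 30,
                     width = 0.8)
  temps <- seq(22, 38, 0.1)
  fit <- fitSigmoid(temps, stRate(m, temps))

  lit <- workingRange(fit, "literal")
  # independent closed form by root-finding on the logistic
  curve <- function(T) 30 + 20 / (1 + exp((T - 30) / 0.8))
  lowExp <- uniroot(function(T) curve(T) - 45, c(20, 30), tol = 1e-10)$root
  highExp <- uniroot(function(T) curve(T) - 33, c(30, 40), tol = 1e-10)$root
  expect_equal(lit@workingLow, lowExp, tolerance = 1e-6)
  expect_equal(lit@workingHigh, highExp, tolerance = 1e-6)
  # the fitted curve reproduces the boundary activities at the returned temps
  expect_equal(curve(lit@workingLow), 0.90 * 50, tolerance = 1e-5)
  expect_equal(curve(lit@workingHigh), 1.10 * 30, tolerance = 1e-5)
  expect_true(lit@workingLow < lit@midpointTemp &&
                lit@midpointTemp < lit@workingHigh)

  # span rule: symmetric about T0 at T0 +/- w ln 9
  sp <- workingRange(fit, "span")
  expect_equal(sp@workingLow, 30 - 0.8 * log(9), tolerance = 1e-5)
  expect_equal(sp@workingHigh, 30 + 0.8 * log(9), tolerance = 1e-5)
})

test_that("the literal working-range rule degenerates at rateLow = 0", {
  m <- STNeuronModel(rateHigh = 50, rateLow = 0, midpointTemp = 30,
                     width = 0.8)
  temps <- seq(22, 38, 0.1)
  fit <- fitSigmoid(temps, stRate(m, temps))
  expect_error(workingRange(fit, "literal"), "degenerates")
  expect_true(workingRange(fit, "span")@workingLow < 30)
})

test_that("span-rule working range is symmetric for arbitrary parameters", {
  set.seed(17)
  for (i in 1:10) {
    m <- STNeuronModel(rateHigh = runif(1, 35, 80), rateLow = runif(1, 0, 30),
                       midpointTemp = runif(1, 28, 32),
                       width = runif(1, 0.3, 2))
    temps <- seq(m@midpointTemp - 8, m@midpointTemp + 8, 0.1)
    fit <- workingRange(fitSigmoid(temps, stRate(m, temps)), "span")
    expect_equal(fit@workingHigh - fit@midpointTemp,
                 fit@midpointTemp - fit@workingLow, tolerance = 1e-4)
  }
})

test_that("ST resolving power linearizes around the turning point", {
  m <- STNeuronModel(rateHigh = 50, rateLow = 29.5, midpointTemp = 30,
                     width = 0.7885)
  temps <- seq(23, 37, 0.1)
  fit <- fitSigmoid(temps, stRate(m, temps))
  out <- stResolvingPower(temps, stRate(m, temps), fit)
  # independent computation from first principles: local OLS by moment
  # formulas, sigma with the n - 1 divisor, then the resolving-power rule
  sel <- abs(temps - fit@midpointTemp) <= 1
  x <- temps[sel]; y <- stRate(m, temps)[sel]
  bLoc <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - mean(y) - bLoc * (x - mean(x))
  sigLoc <- sqrt(sum(resid^2) / (length(x) - 1))
  expect_equal(out@resolvingPowerC, 2 * sigLoc / abs(bLoc) * qnorm(0.9),
               tolerance = 1e-8)
  # noiseless logistic center is near-linear: far below the ~1.6 degC
  # resolving power of realistic noisy units
  expect_lt(out@resolvingPowerC, 0.1)
  expect_gte(out@resolvingPowerC, 0)
  # sigma = 1 APs/s at |b| = 6.5 APs/degC with the tabulated constant
  expect_equal(2 * 1.0 * 1.28 / 6.5, 0.394, tolerance = 1e-3)
  expect_error(stResolvingPower(temps[1:3], stRate(m, temps[1:3]), fit),
               "too few bins")
})

test_that("plateau comparison measures the activity drop and its p-value", {
  same <- c(40, 41, 42, 43)
  out <- plateauComparison(same, same)
  expect_equal(out$drop_pct, 0)
  expect_gte(out$p_value, 0.99)
  expect_equal(plateauComparison(rep(50, 7), rep(29.5, 7))$drop_pct,
               100 * (50 - 29.5) / 50)
  expect_error(plateauComparison(1:4, 1:3), "length mismatch")
  expect_error(plateauComparison(1:2, 1:2), "at least 3")
  # unpaired identical groups: no evidence of a difference
  expect_gte(plateauComparison(same, same, paired = FALSE)$p_value, 0.99)
})
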