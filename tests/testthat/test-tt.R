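test_that("dose-response points keep only supra-noise responses", {
  # two cooling bins above the noise band survive; direction must match
  stim <- data.frame(bin_start = 0:9,
                     mean_temp = 25,
                     changing_rate = c(rep(-0.05, 5), rep(-0.1, 5)))
  act <- data.frame(bin_start = 0:9, median_if = 50,
                    mean_rate = 50, nif = c(rep(150, 5), rep(160, 5)))
  base <- new("BaselineStats", windowStart = -10, windowEnd = 0,
              meanNif = 100, sdNif = 5, noiseLevel = 10, meanRateHz = 40,
              nBins = 10L)
  pts <- collectPoints(act, stim, base, onset = 0, direction = "cooling")
  expect_equal(nrow(pts), 10)
  expect_setequal(round(exp(pts$log_rate), 3), c(0.05, 0.1))

  # responses inside the noise band yield an empty point list
  act$nif <- 100 + c(rep(-5, 5), rep(5, 5))
  expect_equal(nrow(collectPoints(act, stim, base, 0,
                                  direction = "cooling")), 0)
  # heating direction finds nothing in a cooling stimulus
  act$nif <- 150
  expect_equal(nrow(collectPoints(act, stim, base, 0,
                                  direction = "heating")), 0)
})

test_that("per-bin gating truncates while level gating keeps whole levels", {
  stim <- data.frame(bin_start = 0:19, mean_temp = 25,
                     changing_rate = -0.05)
  base <- new("BaselineStats", windowStart = -10, windowEnd = 0,
              meanNif = 100, sdNif = 5, noiseLevel = 10, meanRateHz = 40,
              nBins = 10L)
  nif <- rep(c(108, 116), 10)              # straddles the 110 boundary
  act <- data.frame(bin_start = 0:19, median_if = 50, mean_rate = 50,
                    nif = nif)
  lvl <- collectPoints(act, stim, base, 0, direction = "cooling",
                       select = "level")
  bin <- collectPoints(act, stim, base, 0, direction = "cooling",
                       select = "bin")
  expect_equal(nrow(lvl), 20)              # level mean 112 > 110: all kept
  expect_equal(nrow(bin), 10)              # only bins > 110 survive
  expect_true(all(bin$nif == 116))
})

test_that("log-linear fit recovers an exact Weber-Fechner line", {
  pts <- exactLinePoints(c(0.01, 0.02, 0.05, 0.1), slopeLn = 60 / log(10),
                         theta = 0.01)
  fit <- fitDoseResponse(pts)
  expect_equal(fit@slopeDecade, 60, tolerance = 1e-9)
  expect_equal(fit@slopeLn * log(10), fit@slopeDecade)
  expect_equal(fit@pearsonR, 1)
  expect_equal(fit@residualSd, 0, tolerance = 1e-9)
  expect_lt(fit@pValue, 0.05)              # exact fit: t diverges
  expect_true(fit@qcPass)
  expect_equal(fit@stimNoiseLevel, 2 * fit@residualSd)
})

test_that("QC fails on weak correlation and sign-adapts for heating", {
  set.seed(11)
  n <- 40
  x <- rep(log(c(0.01, 0.03, 0.1, 0.3)), each = 10)
  weak <- data.frame(log_rate = x, nif = 100 + 0.5 * x + rnorm(n, 0, 30),
                     direction = "cooling")
  fitW <- fitDoseResponse(weak)
  expect_false(fitW@qcPass)
  expect_lt(abs(fitW@pearsonR), 0.3 + 1e-9)

  heat <- data.frame(log_rate = x, nif = 80 - 10 * (x - log(0.01)) +
                       rnorm(n, 0, 2), direction = "heating")
  fitH <- fitDoseResponse(heat)
  expect_true(fitH@qcPass)
  expect_lt(fitH@pearsonR, -0.3)

  expect_error(fitDoseResponse(weak[1:3, ]), "too few points")
  same <- data.frame(log_rate = rep(log(0.1), 5), nif = rnorm(5, 120, 2),
                     direction = "cooling")
  expect_error(fitDoseResponse(same), "span")
})

test_that("residual sigma uses the n - 1 divisor", {
  set.seed(21)
  pts <- exactLinePoints(c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5))
  pts$nif <- pts$nif + rnorm(6, 0, 4)
  fit <- fitDoseResponse(pts)
  res <- pts$nif - (fit@intercept + fit@slopeLn * pts$log_rate)
  expect_equal(fit@residualSd, sqrt(sum(res^2) / (nrow(pts) - 1)))
})

test_that("resolving power follows Delta-x = 2 sigma Phi^-1(gamma) / |b|", {
  expect_equal(resolvingPower(0, 10), 0)
  expect_equal(phiInverse(0.9, "tabulated"), 1.28)
  expect_equal(phiInverse(0.9), qnorm(0.9))
  # the printed worked constant: sigma = 0.1453 |b| at gamma 0.9
  expect_equal(resolvingPower(0.1453 * 26.06, 26.06, phiRounding = "tabulated"),
               0.372, tolerance = 1e-3)
  expect_error(resolvingPower(1, 0), "zero slope")
  expect_error(phiInverse(0.4), "gamma")

  # linear in sigma, inversely proportional to |b| on a grid
  grid <- expand.grid(s = c(1, 2, 5), b = c(-20, 10, 40))
  dx <- with(grid, mapply(resolvingPower, s, b))
  expect_equal(dx, with(grid, 2 * s / abs(b) * qnorm(0.9)))
})

test_that("detection threshold is the regression/noise-band crossing", {
  g <- 60 / log(10)
  pts <- exactLinePoints(c(0.01, 0.03, 0.1, 0.3), slopeLn = g, theta = 0.01)
  fit <- fitDoseResponse(pts)
  base0 <- new("BaselineStats", windowStart = -10, windowEnd = 0,
               meanNif = 100, sdNif = 0, noiseLevel = 0, meanRateHz = 40,
               nBins = 10L)
  out0 <- detectionThreshold(fit, base0)
  expect_equal(abs(out0@detectionThreshold), 0.01, tolerance = 1e-9)
  expect_lt(out0@detectionThreshold, 0)        # signed for cooling

  base10 <- new("BaselineStats", windowStart = -10, windowEnd = 0,
                meanNif = 100, sdNif = 5, noiseLevel = 10, meanRateHz = 40,
                nBins = 10L)
  out10 <- detectionThreshold(fit, base10)
  # independent closed form: crossing of 100 + 10 with the known line
  expected <- uniroot(function(r) (100 + g * log(r / 0.01)) - 110,
                      c(1e-4, 1), tol = 1e-12)$root
  expect_equal(abs(out10@detectionThreshold), expected, tolerance = 1e-6)
  expect_equal(out10@thresholdFlag, "fit")

  # crossing below the smallest applied stimulus is floored and flagged
  outF <- detectionThreshold(fit, base0, smallestTested = 0.05)
  expect_equal(abs(outF@detectionThreshold), 0.05)
  expect_equal(outF@thresholdFlag, "below-smallest-tested")

  # a heating-direction line with positive slope never crosses
  fitBad <- fitDoseResponse(pts, direction = "heating")
  expect_error(detectionThreshold(fitBad, base10), "never crosses")
})

test_that("JND conversion reproduces the printed worked examples", {
  expect_equal(round(abs(jnd(-0.1, 0.372)), 3), 0.037)
  expect_equal(round(jnd(-0.047, 0.372), 3), -0.017)
  expect_equal(round(jnd(0.029, 0.275), 3), 0.008)
  expect_error(jnd(0.1, -1), "resolvingPower")
})

test_that("regression recovery: slope inside its 95% CI in most simulations", {
  set.seed(31)
  hits <- 0L
  for (i in 1:200) {
    x <- runif(30, log(0.01), log(0.4))
    y <- 80 + 26 * x + rnorm(30, 0, 5)
    fit <- fitDoseResponse(data.frame(log_rate = x, nif = y,
                                      direction = "cooling"))
    se <- sqrt(sum((y - fit@intercept - fit@slopeLn * x)^2) / 28 /
                 sum((x - mean(x))^2))
    ci <- fit@slopeLn + c(-1, 1) * qt(0.975, 28) * se
    if (ci[1] <= 26 && 26 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 180)
})
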