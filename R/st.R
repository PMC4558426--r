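#' Fit a decreasing logistic to mean rate versus temperature (Gauss-Newton)
#'
#' Least-squares fit of
#' `rate(T) = rateLow + (rateHigh - rateLow) / (1 + exp((T - T0) / w))`
#' by Gauss-Newton iteration with step halving. Starting values are taken
#' from the data: the plateaus from the bin means in the lowest and highest
#' temperature deciles, T0 from where the rate crosses the plateau midpoint,
#' and w from a quarter of the interquartile temperature span. The iteration
#' stops when the scaled gradient norm falls below `tol` or after `maxIter`
#' iterations; the turning-point sensitivity is evaluated in closed form as
#' `-(rateHigh - rateLow) / (4 w)`.
#'
#' @param temps per-bin mean temperatures, degC.
#' @param rates per-bin mean firing rates, APs/s.
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param maxIter maximum Gauss-Newton iterations (default 200).
#' @return a [STFitResult-class] with the fit fields set; working range,
#'   resolving power and plateau comparison are filled by the downstream
#'   steps.
#' @examples
#' m <- STNeuronModel()
#' temps <- seq(24, 36, 0.1)
#' fit <- fitSigmoid(temps, stRate(m, temps))
#' midpointTemp(fit)       # 30
#' slopeAtMidpoint(fit)    # -6.5
#' @export
fitSigmoid <- function(temps, rates, tol = 1e-8, maxIter = 200) {
  ok <- is.finite(temps) & is.finite(rates)
  temps <- temps[ok]; rates <- rates[ok]
  n <- length(temps)
  if (n < 12) stop("need at least 12 bins")
  if (diff(range(temps)) < 4) stop("degenerate span: need >= 4 degC")
  # data-driven initialization
  qs <- stats::quantile(temps, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  rh0 <- mean(rates[temps <= qs[1]])
  rl0 <- mean(rates[temps >= qs[4]])
  if (!(rh0 > rl0)) stop("rates do not decrease with temperature")
  mid <- (rh0 + rl0) / 2
  ord <- order(temps)
  sm <- stats::filter(rates[ord], rep(1 / 9, 9), sides = 2)
  below <- which(!is.na(sm) & sm <= mid)
  T00 <- if (length(below)) temps[ord][below[1]] else median(temps)
  w0 <- max((qs[3] - qs[2]) / 4, 1e-2)
  p <- c(rl = rl0, rh = rh0, T0 = T00, w = w0)
  model <- function(p, x) p[1] + (p[2] - p[1]) / (1 + exp((x - p[3]) / p[4]))
  ssr <- function(p) sum((rates - model(p, temps))^2)
  conv <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    z <- (temps - p[3]) / p[4]
    ez <- exp(z)
    s <- 1 / (1 + ez)                    # logistic factor
    f <- p[1] + (p[2] - p[1]) * s
    r <- rates - f
    dsdz <- -ez * s^2
    J <- cbind(1 - s,                    # d/d rateLow
               s,                        # d/d rateHigh
               (p[2] - p[1]) * dsdz * (-1 / p[4]),   # d/d T0
               (p[2] - p[1]) * dsdz * (-z / p[4]))   # d/d w
    g <- crossprod(J, r)
    if (max(abs(g)) < tol * max(1, ssr(p))) { conv <- TRUE; break }
    step <- tryCatch(solve(crossprod(J), g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- p + lambda * as.numeric(step)
      if (cand[4] > 0 && cand[2] > cand[1] && ssr(cand) < ssr(p)) {
        p <- cand
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {                     # no descent direction left
      conv <- max(abs(g)) < sqrt(tol) * max(1, ssr(p))
      break
    }
  }
  new("STFitResult",
      rateHigh = unname(p[2]), rateLow = unname(p[1]),
      midpointTemp = unname(p[3]), width = unname(p[4]),
      slopeAtMidpoint = unname(-(p[2] - p[1]) / (4 * p[4])),
      workingLow = NA_real_, workingHigh = NA_real_,
      workingRule = NA_character_, resolvingPowerC = NA_real_,
      plateauLowTempRate = NA_real_, plateauHighTempRate = NA_real_,
      plateauDropPct = NA_real_, converged = conv,
      iterations = as.integer(it), nBins = as.integer(n))
}

# invert the fitted logistic: temperature at which the curve equals `a`
invertLogistic <- function(fit, a) {
  if (a <= fit@rateLow || a >= fit@rateHigh)
    stop("boundary activity outside the open interval (rateLow, rateHigh)")
  fit@midpointTemp +
    fit@width * log((fit@rateHigh - a) / (a - fit@rateLow))
}

#' Working range of a fitted ST-neuron
#'
#' The temperature interval over which the neuron's steady activity varies,
#' bounded by a 10 percent departure from its two plateaus. Two readings of
#' the rule are provided: `"literal"` (default) places the boundaries at
#' activities `0.90 * rateHigh` and `1.10 * rateLow`; `"span"` places them
#' 10 percent of the plateau-to-plateau span inside each plateau
#' (`rateHigh - 0.10 * span` and `rateLow + 0.10 * span`), which is
#' symmetric about T0 and remains defined when `rateLow` approaches zero.
#' Boundary activities are inverted through the fitted logistic.
#'
#' @param fit a converged [STFitResult-class].
#' @param rule `"literal"` or `"span"`.
#' @return the input fit with `workingLow`, `workingHigh` and `workingRule`
#'   filled; `workingLow < midpointTemp < workingHigh`.
#' @examples
#' m <- STNeuronModel(rateHigh = 50, rateLow = 30, midpointTemp = 30,
#'                    width = 0.8)
#' temps <- seq(24, 36, 0.1)
#' fit <- workingRange(fitSigmoid(temps, stRate(m, temps)))
#' c(fit@workingLow, fit@workingHigh)
#' @export
workingRange <- function(fit, rule = c("literal", "span")) {
  rule <- match.arg(rule)
  if (!isTRUE(fit@converged)) stop("fit did not converge")
  span <- fit@rateHigh - fit@rateLow
  bounds <- switch(rule,
    literal = {
      if (fit@rateLow <= 1e-6 * fit@rateHigh)
        stop("literal rule degenerates when rateLow = 0 (1.10 * 0 is never attained); use rule = 'span'")
      c(0.90 * fit@rateHigh, 1.10 * fit@rateLow)
    },
    span = c(fit@rateHigh - 0.10 * span, fit@rateLow + 0.10 * span))
  lo <- invertLogistic(fit, bounds[1])   # high activity -> low temperature
  hi <- invertLogistic(fit, bounds[2])
  fit@workingLow <- lo
  fit@workingHigh <- hi
  fit@workingRule <- rule
  validObject(fit)
  fit
}

#' Resolving power of a ST-neuron for steady-state temperature
#'
#' Linearizes the fitted sigmoid around the turning point (highest
#' sensitivity): ordinary least squares of mean rate on temperature over the
#' bins within `halfWindow` degC of T0, then
#' `Delta-x = (2 sigma / |b|) * PhiInv(gamma)` in degrees C, with sigma the
#' residual SD (n - 1 divisor) of that local regression.
#'
#' @param temps,rates the per-bin data used for the fit.
#' @param fit a [STFitResult-class].
#' @param halfWindow half-width of the linearization window, degC (default 1).
#' @param gamma required detection probability (default 0.9).
#' @param phiRounding see [phiInverse()].
#' @param minBins minimum number of bins in the window (default 4).
#' @return the input fit with `resolvingPowerC` filled (degC).
#' @export
stResolvingPower <- function(temps, rates, fit, halfWindow = 1, gamma = 0.9,
                             phiRounding = c("exact", "tabulated"), minBins = 4) {
  sel <- is.finite(temps) & is.finite(rates) &
    abs(temps - fit@midpointTemp) <= halfWindow
  if (sum(sel) < minBins)
    stop(sprintf("too few bins within +/-%g degC of the turning point",
                 halfWindow))
  x <- temps[sel]; y <- rates[sel]
  loc <- lm(y ~ x)
  b <- unname(coef(loc)[2])
  if (b == 0) stop("zero slope in the linearization window")
  sigma <- sqrt(sum(stats::residuals(loc)^2) / (length(x) - 1))
  fit@resolvingPowerC <- resolvingPower(sigma, b, gamma, phiRounding)
  fit
}

#' Compare the two activity plateaus of ST-neurons
#'
#' The relative drop between the low-temperature and high-temperature
#' activity levels, and a rank test of the difference: Wilcoxon signed-rank
#' when the levels are paired per recording (default), Wilcoxon rank-sum
#' otherwise.
#'
#' @param ratesLowTemp per-recording mean rates below the working range
#'   (high-activity plateau), APs/s.
#' @param ratesHighTemp per-recording mean rates above the working range
#'   (low-activity plateau), APs/s.
#' @param paired lists are paired by recording (default TRUE).
#' @return list with `drop_pct` (percent of the low-temperature level) and
#'   `p_value`.
#' @examples
#' plateauComparison(c(48, 52, 50), c(30, 29, 30))$drop_pct
#' @export
plateauComparison <- function(ratesLowTemp, ratesHighTemp, paired = TRUE) {
  if (length(ratesLowTemp) < 3 || length(ratesHighTemp) < 3)
    stop("need at least 3 values per level")
  if (paired && length(ratesLowTemp) != length(ratesHighTemp))
    stop("length mismatch in paired mode")
  dropPct <- 100 * (mean(ratesLowTemp) - mean(ratesHighTemp)) /
    mean(ratesLowTemp)
  p <- if (paired && all(ratesLowTemp == ratesHighTemp)) 1
  else suppressWarnings(
    wilcox.test(ratesLowTemp, ratesHighTemp, paired = paired,
                exact = FALSE)$p.value)
  if (is.na(p)) p <- 1
  list(drop_pct = dropPct, p_value = p)
}
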