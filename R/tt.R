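#' Collect dose-response points from one recording
#'
#' Pairs each response bin of the stimulation phase with that bin's
#' temperature changing rate, on the Weber-Fechner (log) stimulus scale. The
#' stimulation phase starts at `onset` and extends while the absolute
#' smoothed changing rate stays at or above `rateFloor` (short sub-floor gaps
#' up to `grace` bins are tolerated), capped at `window` seconds after onset;
#' this keeps the regression to bins recorded during stimulation and excludes
#' the adaptation tail at the plateau, where the changing rate is nominally
#' zero but the activity is still relaxing.
#'
#' Response gating against the resting noise level is applied per stimulus
#' level (`select = "level"`, default): the whole stimulation phase is kept
#' when its mean nIF departs from 100 by more than the noise level in the
#' response direction, and dropped otherwise. Gating each bin individually
#' (`select = "bin"`) is the more literal reading of thresholding single nIF
#' values, but truncating observations at the noise boundary biases the
#' subsequent regression slope toward zero; see the package vignette.
#'
#' @param activity data.frame from [normalizeNif()] (with `nif` filled).
#' @param stim data.frame from [binStimulus()].
#' @param baseline a [BaselineStats-class].
#' @param onset stimulus onset, seconds.
#' @param window response window after onset, seconds (default 240).
#' @param direction `"cooling"` or `"heating"`: which stimulus sign to keep.
#'   Cooling responses are excitatory (nIF above 100 + noise), heating
#'   responses suppressive (nIF below 100 - noise). Complete silencing (bins
#'   without IF samples) yields missing nIF and is excluded from regression.
#' @param rateFloor minimum absolute changing rate for a bin to count as
#'   stimulation, degC/s (default 0.005).
#' @param select `"level"` (default) or `"bin"` response gating, see above.
#' @param grace tolerated consecutive sub-floor bins inside the phase.
#' @return data.frame with columns `log_rate` (ln of the absolute changing
#'   rate), `nif` (percent) and `direction`; zero rows when no bin qualifies.
#' @export
collectPoints <- function(activity, stim, baseline, onset, window = 240,
                          direction = c("cooling", "heating"),
                          rateFloor = 0.005, select = c("level", "bin"),
                          grace = 2) {
  direction <- match.arg(direction)
  select <- match.arg(select)
  df <- merge(activity, stim, by = "bin_start")
  df <- df[order(df$bin_start), ]
  df <- df[df$bin_start >= onset & df$bin_start < onset + window, ]
  if (!nrow(df)) return(emptyPoints(direction))
  # contiguous stimulation phase from onset; once the applied intensity is
  # known (median of the first supra-floor bins) a bin must retain at least
  # half of it to continue the phase, so the adaptation tail at the plateau
  # (nominal rate ~0, activity still relaxing) never leaks into the points
  absRate <- abs(df$changing_rate)
  first <- which(absRate >= rateFloor)
  if (!length(first)) return(emptyPoints(direction))
  levelRate0 <- median(absRate[first[1]:min(first[1] + 2L, nrow(df))])
  keepRate <- max(rateFloor, 0.5 * levelRate0)
  supra <- absRate >= keepRate
  phaseEnd <- 0L
  miss <- 0L
  for (i in first[1]:nrow(df)) {
    if (supra[i]) {
      phaseEnd <- i
      miss <- 0L
    } else {
      miss <- miss + 1L
      if (miss > grace) break
    }
  }
  if (phaseEnd == 0L) return(emptyPoints(direction))
  df <- df[seq_len(phaseEnd), ]
  wantSign <- if (direction == "cooling") -1 else 1
  df <- df[supra[seq_len(phaseEnd)] &
             sign(df$changing_rate) == wantSign &
             !is.na(df$nif), ]
  if (!nrow(df)) return(emptyPoints(direction))
  levelRate <- median(abs(df$changing_rate))   # applied stimulus intensity
  noise <- baseline@noiseLevel
  responding <- if (direction == "cooling") df$nif > 100 + noise
                else df$nif < 100 - noise
  levelResponds <- if (direction == "cooling") mean(df$nif) > 100 + noise
                   else mean(df$nif) < 100 - noise
  keep <- switch(select,
    level = rep(levelResponds, nrow(df)),
    bin = responding)
  df <- df[keep, ]
  if (!nrow(df)) return(emptyPoints(direction, levelRate))
  out <- data.frame(log_rate = log(abs(df$changing_rate)), nif = df$nif,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "levelRate") <- levelRate
  out
}

emptyPoints <- function(direction, levelRate = NA_real_) {
  out <- data.frame(log_rate = numeric(), nif = numeric(),
                    direction = character(), stringsAsFactors = FALSE)
  attr(out, "levelRate") <- levelRate
  out
}

#' Fit the log-linear (Weber-Fechner) dose-response regression
#'
#' Ordinary least squares of nIF on the natural log of the absolute
#' temperature changing rate. Reports the slope per ln-unit and per decade
#' (differential sensitivity), the Pearson correlation, the two-sided
#' p-value of the slope, the residual standard deviation sigma (with an
#' n - 1 divisor) and the stimulation noise level 2 sigma. Quality control
#' passes when p < 0.05 and the Pearson correlation exceeds 0.3 (cooling) or
#' falls below -0.3 (heating).
#'
#' @param points data.frame from [collectPoints()] (possibly pooled over
#'   recordings of one unit); needs at least `minPoints` points spanning at
#'   least `minSpan` ln-units of stimulus.
#' @param direction `"cooling"` or `"heating"`; defaults to the direction
#'   recorded in `points`.
#' @param baseline optional [BaselineStats-class]; its noise level is stored
#'   for the later detection-threshold step.
#' @param minPoints,minSpan admissibility bounds (defaults 4 and 0.5).
#' @return a [TTFitResult-class] with threshold and resolving power unset.
#' @examples
#' pts <- data.frame(log_rate = log(c(0.01, 0.03, 0.1, 0.3)),
#'                   nif = 100 + 26.06 * log(c(0.01, 0.03, 0.1, 0.3) / 0.01),
#'                   direction = "cooling")
#' fit <- fitDoseResponse(pts)
#' slopeDecade(fit)    # 60 %/decade
#' @export
fitDoseResponse <- function(points, direction = NULL, baseline = NULL,
                            minPoints = 4, minSpan = 0.5) {
  if (is.null(direction)) {
    direction <- unique(as.character(points$direction))
    if (length(direction) != 1L)
      stop("points must carry a single direction (or pass `direction`)")
  }
  n <- nrow(points)
  if (n < minPoints) stop(sprintf("too few points: %d < %d", n, minPoints))
  span <- diff(range(points$log_rate))
  if (span < minSpan)
    stop(sprintf("stimulus span %.3g ln-units below minimum %.3g",
                 span, minSpan))
  fit <- lm(nif ~ log_rate, data = points)
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1])
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / (n - 1))
  r <- cor(points$log_rate, points$nif)
  # two-sided slope p-value via the t distribution; exact fits get p = 0
  s2 <- sum(res^2) / (n - 2)
  sxx <- sum((points$log_rate - mean(points$log_rate))^2)
  p <- if (s2 <= 0) 0 else 2 * pt(-abs(b / sqrt(s2 / sxx)), df = n - 2)
  qc <- p < 0.05 && if (direction == "cooling") r > 0.3 else r < -0.3
  new("TTFitResult",
      direction = direction, slopeLn = b, slopeDecade = b * log(10),
      intercept = a, pearsonR = r, pValue = p, residualSd = sigma,
      stimNoiseLevel = 2 * sigma,
      baselineNoise = if (is.null(baseline)) NA_real_ else baseline@noiseLevel,
      nPoints = as.integer(n), qcPass = qc,
      detectionThreshold = NA_real_, thresholdFlag = NA_character_,
      resolvingPower = NA_real_)
}

#' Inverse standard-normal quantile used by the resolving power
#'
#' @param gamma required detection probability, in (0.5, 1).
#' @param phiRounding `"exact"` uses `qnorm(gamma)`; `"tabulated"` rounds it to
#'   two decimals (the tabulated constant 1.28 at gamma = 0.9).
#' @return the quantile, dimensionless.
#' @export
phiInverse <- function(gamma = 0.9, phiRounding = c("exact", "tabulated")) {
  if (gamma <= 0.5 || gamma >= 1) stop("gamma must be in (0.5, 1)")
  phiRounding <- match.arg(phiRounding)
  q <- qnorm(gamma)
  if (phiRounding == "tabulated") q <- round(q, 2)
  q
}

#' Resolving power of a log-linear dose-response fit
#'
#' `Delta-x = (2 sigma / |b|) * PhiInv(gamma)`: the relative stimulus change
#' needed for a response distinguishable from the regression with
#' probability `gamma`, where `sigma` is the residual SD of the nIF about
#' the regression and `b` the regression slope per ln-unit. Dimensionless on
#' the log-stimulus scale; multiply by the stimulus intensity ([jnd()]) to
#' obtain the just-noticeable stimulus difference.
#'
#' @param residualSd sigma, nIF percent.
#' @param slopeLn regression slope b, nIF percent per ln-unit (nonzero).
#' @param gamma required detection probability (default 0.9).
#' @param phiRounding see [phiInverse()].
#' @return Delta-x, dimensionless (>= 0).
#' @examples
#' resolvingPower(0.1453 * 26.06, 26.06, phiRounding = "tabulated")  # 0.372
#' @export
resolvingPower <- function(residualSd, slopeLn, gamma = 0.9,
                           phiRounding = c("exact", "tabulated")) {
  if (slopeLn == 0) stop("zero slope")
  2 * residualSd / abs(slopeLn) * phiInverse(gamma, phiRounding)
}

#' Detection threshold from a dose-response fit
#'
#' The smallest temperature changing rate whose fitted response departs from
#' the resting activity by more than the noise level: the stimulus magnitude
#' at which the regression line crosses `100 + noise` (cooling) or
#' `100 - noise` (heating). When the crossing lies below the smallest
#' stimulus actually applied, that smallest tested intensity is returned and
#' flagged.
#'
#' @param fit a [TTFitResult-class].
#' @param baseline a [BaselineStats-class] supplying the resting noise level
#'   (optional if the fit already carries it).
#' @param smallestTested smallest applied stimulus magnitude, degC/s
#'   (optional).
#' @return a [TTFitResult-class] with `detectionThreshold` (signed by
#'   direction) and `thresholdFlag` filled.
#' @export
detectionThreshold <- function(fit, baseline = NULL, smallestTested = NULL) {
  noise <- if (!is.null(baseline)) baseline@noiseLevel else fit@baselineNoise
  if (!is.finite(noise)) stop("no baseline noise level available")
  b <- fit@slopeLn
  if (fit@direction == "cooling" && b <= 0)
    stop("cooling requires a positive slope: the line never crosses the noise band")
  if (fit@direction == "heating" && b >= 0)
    stop("heating requires a negative slope: the line never crosses the noise band")
  target <- if (fit@direction == "cooling") 100 + noise else 100 - noise
  magnitude <- exp((target - fit@intercept) / b)
  flag <- "fit"
  if (!is.null(smallestTested) && magnitude < smallestTested) {
    magnitude <- smallestTested
    flag <- "below-smallest-tested"
  }
  fit@baselineNoise <- noise
  fit@detectionThreshold <-
    if (fit@direction == "cooling") -magnitude else magnitude
  fit@thresholdFlag <- flag
  fit
}

#' Just-noticeable stimulus difference at a given stimulus intensity
#'
#' First-order conversion of the dimensionless log-scale resolving power
#' into a stimulus difference: `jnd = resolvingPower * rate` (signed like
#' the stimulus; its magnitude is the smallest noticeable change).
#'
#' @param stimulusRate temperature changing rate, degC/s (signed).
#' @param resolvingPower dimensionless Delta-x (>= 0).
#' @return stimulus difference in degC/s, signed like `stimulusRate`.
#' @examples
#' jnd(-0.1, 0.372)     # -0.0372: a neuron driven at -0.1 degC/s resolves
#'                      # changes of ~0.037 degC/s
#' @export
jnd <- function(stimulusRate, resolvingPower) {
  if (any(resolvingPower < 0)) stop("resolvingPower must be >= 0")
  resolvingPower * stimulusRate
}
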