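#' Analysis configuration
#'
#' Bundles the tunable analysis parameters with their defaults: Gaussian
#' smoothing width 0.5 s, 1-s bins, 240-s response window, 10-s baseline,
#' stimulation rate floor 0.005 degC/s, detection probability gamma 0.9
#' with exact inverse-normal quantile, level-wise response gating, and the
#' literal working-range rule.
#'
#' @param smoothSigma Gaussian smoothing width, s.
#' @param binWidth bin width, s.
#' @param window TT response window after onset, s.
#' @param baselineLen baseline window, s.
#' @param rateFloor stimulation rate floor, degC/s.
#' @param gamma required detection probability for resolving powers.
#' @param phiRounding `"exact"` or `"tabulated"` (see [phiInverse()]).
#' @param select TT response gating, `"level"` or `"bin"`.
#' @param workingRule ST working-range rule, `"literal"` or `"span"`.
#' @return a named list of class `"thermoConfig"`.
#' @export
thermoConfig <- function(smoothSigma = 0.5, binWidth = 1, window = 240,
                         baselineLen = 10, rateFloor = 0.005, gamma = 0.9,
                         phiRounding = "exact", select = "level",
                         workingRule = "literal") {
  structure(list(smoothSigma = smoothSigma, binWidth = binWidth,
                 window = window, baselineLen = baselineLen,
                 rateFloor = rateFloor, gamma = gamma,
                 phiRounding = phiRounding, select = select,
                 workingRule = workingRule),
            class = "thermoConfig")
}

#' Read a recording from CSV files
#'
#' Reads a temperature trace (`time_s`, `temp_c`) and a sorted spike list
#' (`spike_time_s`), validates them (no missing values, strictly increasing
#' times, spikes inside the trace span with a one-sample-interval tolerance)
#' and assembles a [Recording-class]. Sampling gaps longer than three
#' nominal intervals are reported as a warning and analysis proceeds.
#'
#' @param tempPath path to the temperature CSV.
#' @param spikesPath path to the spikes CSV.
#' @param unitId unit identifier.
#' @param neuronClass `"TT"`, `"ST"` or `"unknown"`.
#' @param protocolOnset stimulus onset in seconds when known from the
#'   protocol (overrides detection downstream), else NA.
#' @return a [Recording-class].
#' @export
readRecording <- function(tempPath, spikesPath, unitId = "unit1",
                          neuronClass = "unknown", protocolOnset = NA_real_) {
  tempDf <- utils::read.csv(tempPath)
  if (!all(c("time_s", "temp_c") %in% names(tempDf)))
    stop("temperature file must have columns time_s, temp_c")
  if (!nrow(tempDf)) stop("empty temperature file")
  if (anyNA(tempDf$time_s) || anyNA(tempDf$temp_c))
    stop("temperature file contains missing values")
  spikeDf <- utils::read.csv(spikesPath)
  if (!"spike_time_s" %in% names(spikeDf))
    stop("spikes file must have column spike_time_s")
  sp <- spikeDf$spike_time_s
  if (anyNA(sp)) stop("spikes file contains missing values")
  bad <- which(diff(sp) <= 0)
  if (length(bad))
    stop(sprintf("unsorted or duplicate spike times at index %d", bad[1] + 1L))
  dt <- median(diff(tempDf$time_s))
  gaps <- which(diff(tempDf$time_s) > 3 * dt)
  if (length(gaps))
    warning(sprintf("%d sampling gap(s) longer than 3 intervals (first after t = %.3g s); affected bins are unreliable",
                    length(gaps), tempDf$time_s[gaps[1]]))
  if (length(sp) && (min(sp) < tempDf$time_s[1] - dt ||
                     max(sp) > tempDf$time_s[nrow(tempDf)] + dt))
    stop("spike times fall outside the temperature trace span")
  Recording(TemperatureTrace(tempDf$time_s, tempDf$temp_c), SpikeTrain(sp),
            unitId = unitId, neuronClass = neuronClass,
            protocolOnset = protocolOnset)
}

# run `expr`, rethrowing errors annotated with unit and stage
withStage <- function(unit, name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("unit %s [%s]: %s", unit, name, conditionMessage(e)),
         call. = FALSE))
}

# shared preprocessing: smooth, bin stimulus, locate onset, bin activity
prepareRecording <- function(rec, config) {
  uid <- unitId(rec)
  sm <- withStage(uid, "smooth", gaussSmooth(rec@trace, config$smoothSigma))
  stim <- withStage(uid, "bin_stimulus", binStimulus(sm, config$binWidth))
  onset <- if (is.finite(rec@protocolOnset)) rec@protocolOnset
  else withStage(uid, "detect_onset", detectOnset(stim, config$rateFloor))
  activity <- withStage(uid, "bin_activity",
                        binActivity(rec@train, stim, config$binWidth))
  list(stim = stim, onset = onset, activity = activity)
}

# TT branch for one recording: nIF normalization and dose-response points
ttBranch <- function(rec, config, direction = "cooling") {
  uid <- unitId(rec)
  prep <- prepareRecording(rec, config)
  norm <- withStage(uid, "normalize_nif",
                    normalizeNif(prep$activity, prep$onset,
                                 config$baselineLen))
  points <- withStage(uid, "collect_points",
                      collectPoints(norm$activity, prep$stim, norm$baseline,
                                    prep$onset, config$window, direction,
                                    config$rateFloor, config$select))
  list(points = points, baseline = norm$baseline, onset = prep$onset,
       stim = prep$stim, activity = norm$activity)
}

#' Characterize one TT-neuron from its recordings
#'
#' Pools dose-response points over one unit's recordings (one stimulation
#' per recording, typically several ramp rates), fits the log-linear
#' regression with QC, and fills in the detection threshold (against the
#' mean resting noise level over recordings, using the smallest applied
#' stimulus as the floor) and the resolving power.
#'
#' @param recs a [Recording-class] or list of them, all from the same unit.
#' @param direction `"cooling"` or `"heating"`.
#' @param config a [thermoConfig()] list.
#' @return a [TTFitResult-class].
#' @export
analyzeTTUnit <- function(recs, direction = "cooling",
                          config = thermoConfig()) {
  if (is(recs, "Recording")) recs <- list(recs)
  branches <- lapply(recs, ttBranch, config = config, direction = direction)
  points <- do.call(rbind, lapply(branches, `[[`, "points"))
  noise <- mean(vapply(branches, function(b) b$baseline@noiseLevel,
                       numeric(1)))
  smallest <- suppressWarnings(
    min(vapply(branches, function(b) attr(b$points, "levelRate"),
               numeric(1)), na.rm = TRUE))
  if (!is.finite(smallest)) smallest <- NULL
  if (is.null(points) || !nrow(points))
    stop(sprintf("unit %s [fit_dose_response]: no supra-noise dose-response points",
                 unitId(recs[[1]])))
  fit <- withStage(unitId(recs[[1]]), "fit_dose_response",
                   fitDoseResponse(points, direction = direction))
  fit@baselineNoise <- noise
  fit <- withStage(unitId(recs[[1]]), "detection_threshold",
                   detectionThreshold(fit, smallestTested = smallest))
  fit@resolvingPower <- resolvingPower(fit@residualSd, fit@slopeLn,
                                       config$gamma, config$phiRounding)
  fit
}

#' Characterize one ST-neuron recording
#'
#' Fits the decreasing logistic to mean rate versus bin temperature over the
#' warming segment (bins whose changing rate is not below minus the rate
#' floor, i.e. excluding the cooling return ramp), then fills the working
#' range, the turning-point resolving power, and the observed plateau
#' activities outside the working range.
#'
#' @param rec a [Recording-class].
#' @param config a [thermoConfig()] list.
#' @return a [STFitResult-class].
#' @export
analyzeST <- function(rec, config = thermoConfig()) {
  uid <- unitId(rec)
  prep <- prepareRecording(rec, config)
  df <- merge(prep$activity, prep$stim, by = "bin_start")
  df <- df[df$changing_rate > -config$rateFloor, ]   # drop the return ramp
  fit <- withStage(uid, "fit_sigmoid",
                   fitSigmoid(df$mean_temp, df$mean_rate))
  fit <- withStage(uid, "working_range",
                   workingRange(fit, config$workingRule))
  fit <- withStage(uid, "st_resolving_power",
                   stResolvingPower(df$mean_temp, df$mean_rate, fit,
                                    gamma = config$gamma,
                                    phiRounding = config$phiRounding))
  lowBins <- df$mean_rate[df$mean_temp < fit@workingLow]
  highBins <- df$mean_rate[df$mean_temp > fit@workingHigh]
  if (length(lowBins)) fit@plateauLowTempRate <- mean(lowBins)
  if (length(highBins)) fit@plateauHighTempRate <- mean(highBins)
  if (length(lowBins) && length(highBins) && mean(lowBins) > 0)
    fit@plateauDropPct <- 100 * (mean(lowBins) - mean(highBins)) /
      mean(lowBins)
  fit
}

#' Run the full analysis on one recording
#'
#' Dispatches on the recording's neuron class: the TT branch (nIF
#' normalization, dose-response points, log-linear fit with threshold and
#' resolving power), the ST branch (sigmoid fit, working range, resolving
#' power), or both for class `"unknown"`. Stage errors are annotated with
#' the unit id and stage name; for class `"unknown"` a failing branch is
#' reported in the result rather than raised.
#'
#' @param rec a [Recording-class].
#' @param config a [thermoConfig()] list.
#' @param direction TT stimulus direction (default `"cooling"`).
#' @return a list with elements `unit_id`, `neuron_class`, and `tt` and/or
#'   `st` (fit results; for `"unknown"`, a failed branch holds the error
#'   message instead).
#' @export
runRecording <- function(rec, config = thermoConfig(),
                         direction = "cooling") {
  out <- list(unit_id = unitId(rec), neuron_class = neuronClass(rec))
  runTT <- function() analyzeTTUnit(rec, direction, config)
  runST <- function() analyzeST(rec, config)
  if (neuronClass(rec) == "TT") {
    out$tt <- runTT()
  } else if (neuronClass(rec) == "ST") {
    out$st <- runST()
  } else {
    out$tt <- tryCatch(runTT(), error = function(e) conditionMessage(e))
    out$st <- tryCatch(runST(), error = function(e) conditionMessage(e))
  }
  out
}

#' One cohort-table row from a TT fit
#'
#' @param fit a [TTFitResult-class].
#' @param unit_id unit identifier.
#' @return a one-row data.frame with the per-unit TT parameters.
#' @export
ttResultRow <- function(fit, unit_id) {
  data.frame(unit_id = unit_id, direction = fit@direction,
             slope_decade = fit@slopeDecade, intercept = fit@intercept,
             pearson_r = fit@pearsonR, p_value = fit@pValue,
             sigma = fit@residualSd, baseline_noise = fit@baselineNoise,
             detection_threshold = fit@detectionThreshold,
             resolving_power = fit@resolvingPower, qc_pass = fit@qcPass,
             n_points = fit@nPoints, stringsAsFactors = FALSE)
}

#' One cohort-table row from a ST fit
#'
#' @param fit a [STFitResult-class].
#' @param unit_id unit identifier.
#' @return a one-row data.frame with the per-unit ST parameters.
#' @export
stResultRow <- function(fit, unit_id) {
  data.frame(unit_id = unit_id, rate_high = fit@rateHigh,
             rate_low = fit@rateLow, t0 = fit@midpointTemp,
             width = fit@width, slope_at_midpoint = fit@slopeAtMidpoint,
             working_low = fit@workingLow, working_high = fit@workingHigh,
             resolving_power_c = fit@resolvingPowerC,
             plateau_drop_pct = fit@plateauDropPct,
             converged = fit@converged, n_bins = fit@nBins,
             stringsAsFactors = FALSE)
}

#' Cohort summary statistics
#'
#' Per-parameter summaries (mean, SD, median, min, max, n) over a cohort
#' results table, Pearson correlations (with two-sided p) for configured
#' parameter pairs, and Mann-Whitney comparisons for a configured group
#' split. Correlations over zero-variance columns are reported as NA (not
#' computable), never as 1. Exploratory p-values are reported unadjusted,
#' with a Holm-adjusted column alongside.
#'
#' @param results data.frame of per-unit rows ([ttResultRow()] /
#'   [stResultRow()] stacked).
#' @param correlate list of 2-element character vectors: column pairs to
#'   correlate.
#' @param compareBy optional name of a logical/factor column splitting the
#'   cohort into two groups for Mann-Whitney comparisons of every numeric
#'   parameter.
#' @return list with data.frames `summaries`, `correlations` and
#'   `comparisons` (NULL when not requested).
#' @export
cohortSummary <- function(results, correlate = list(), compareBy = NULL) {
  if (nrow(results) < 2) stop("need at least 2 results to summarize")
  num <- names(results)[vapply(results, is.numeric, logical(1))]
  summaries <- do.call(rbind, lapply(num, function(cn) {
    x <- results[[cn]]
    x <- x[is.finite(x)]
    data.frame(parameter = cn, mean = mean(x), sd = sd(x),
               median = median(x), min = min(x), max = max(x),
               n = length(x), stringsAsFactors = FALSE)
  }))
  correlations <- NULL
  if (length(correlate)) {
    correlations <- do.call(rbind, lapply(correlate, function(pair) {
      x <- results[[pair[1]]]; y <- results[[pair[2]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
        return(data.frame(x = pair[1], y = pair[2], pearson_r = NA_real_,
                          p = NA_real_, n = sum(ok),
                          stringsAsFactors = FALSE))
      ct <- cor.test(x[ok], y[ok])
      data.frame(x = pair[1], y = pair[2], pearson_r = unname(ct$estimate),
                 p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
    }))
    correlations$p_holm <- stats::p.adjust(correlations$p, "holm")
  }
  comparisons <- NULL
  if (!is.null(compareBy) && compareBy %in% names(results)) {
    g <- results[[compareBy]]
    lev <- unique(g[!is.na(g)])
    if (length(lev) == 2) {
      comparisons <- do.call(rbind, lapply(setdiff(num, compareBy),
                                           function(cn) {
        x <- results[[cn]][g == lev[1]]
        y <- results[[cn]][g == lev[2]]
        x <- x[is.finite(x)]; y <- y[is.finite(y)]
        if (length(x) < 2 || length(y) < 2) return(NULL)
        w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
        data.frame(parameter = cn, group1 = as.character(lev[1]),
                   group2 = as.character(lev[2]),
                   W = unname(w$statistic), p = w$p.value,
                   n1 = length(x), n2 = length(y),
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(comparisons))
        comparisons$p_holm <- stats::p.adjust(comparisons$p, "holm")
    }
  }
  list(summaries = summaries, correlations = correlations,
       comparisons = comparisons)
}

#' Write cohort reports
#'
#' Writes the per-unit results table, the summary tables and per-unit JSON
#' records to a directory, plus a run manifest (package version, analysis
#' configuration and its MD5 hash, seeds). Reruns with identical inputs and
#' configuration produce byte-identical files.
#'
#' @param summary output of [cohortSummary()] (or NULL to skip).
#' @param results data.frame of per-unit rows (may have zero rows).
#' @param outDir output directory (created if missing).
#' @param config a [thermoConfig()] list, recorded in the manifest.
#' @param seeds optional seeds to record in the manifest.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(summary, results, outDir, config = thermoConfig(),
                        seeds = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character()
  if (!is.null(results) && nrow(results)) {
    p <- file.path(outDir, "cohort_results.csv")
    utils::write.csv(results, p, row.names = FALSE)
    paths <- c(paths, p)
    for (i in seq_len(nrow(results))) {
      pj <- file.path(outDir, sprintf("unit_%s.json", results$unit_id[i]))
      jsonlite::write_json(as.list(results[i, ]), pj, auto_unbox = TRUE,
                           digits = NA)
      paths <- c(paths, pj)
    }
  } else {
    warning("empty results list: writing manifest only")
  }
  if (!is.null(summary)) {
    for (nm in names(summary)) {
      if (is.null(summary[[nm]])) next
      p <- file.path(outDir, sprintf("cohort_%s.csv", nm))
      utils::write.csv(summary[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  manifestPath <- file.path(outDir, "manifest.json")
  configJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
  tf <- tempfile(); writeLines(configJson, tf)
  manifest <- list(
    tool = "thermocode",
    version = as.character(utils::packageVersion("thermocode")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tf)),
    seeds = seeds,
    n_units = if (is.null(results)) 0L else nrow(results))
  unlink(tf)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, manifestPath))
}

#' Reproduce the resolving-power worked examples
#'
#' Computes the inverse-normal constant at gamma = 0.9 and converts three
#' (stimulus rate, resolving power) pairs into just-noticeable stimulus
#' differences: a cooling-driven neuron at -0.1 degC/s with resolving power
#' 0.372, the mean cooling detection threshold -0.047 degC/s with resolving
#' power 0.372, and the mean heating detection threshold 0.029 degC/s with
#' resolving power 0.275.
#'
#' @param quiet suppress printing.
#' @return data.frame with columns `quantity`, `value` (invisible when
#'   printed).
#' @examples
#' reproduceWorkedExamples(quiet = TRUE)
#' @export
reproduceWorkedExamples <- function(quiet = FALSE) {
  out <- data.frame(
    quantity = c("phi_inverse_0.9",
                 "jnd_at_-0.1_rp_0.372",
                 "jnd_at_-0.047_rp_0.372",
                 "jnd_at_0.029_rp_0.275"),
    value = c(round(phiInverse(0.9), 2),
              round(jnd(-0.1, 0.372), 3),
              round(jnd(-0.047, 0.372), 3),
              round(jnd(0.029, 0.275), 3)),
    units = c("", "degC/s", "degC/s", "degC/s"),
    stringsAsFactors = FALSE)
  if (!quiet) print(out, row.names = FALSE)
  invisible(out)
}
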