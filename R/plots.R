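utils::globalVariables(c("log_rate", "nif", "x", "y", "temp", "rate"))

#' Diagnostic plot of a TT dose-response fit
#'
#' Dose-response points on the log-stimulus axis with the fitted regression
#' line, its 2-sigma stimulation noise band, and the resting-activity noise
#' band. Requires ggplot2.
#'
#' @param points data.frame from [collectPoints()].
#' @param fit a [TTFitResult-class].
#' @return a ggplot object.
#' @export
plotDoseResponse <- function(points, fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  xr <- range(points$log_rate)
  lineDf <- data.frame(x = seq(xr[1], xr[2], length.out = 50))
  lineDf$y <- fit@intercept + fit@slopeLn * lineDf$x
  g <- ggplot2::ggplot(points, ggplot2::aes(x = log_rate,
                                            y = nif)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_ribbon(data = lineDf,
                         ggplot2::aes(x = x, y = NULL,
                                      ymin = y - fit@stimNoiseLevel,
                                      ymax = y + fit@stimNoiseLevel),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(data = lineDf, ggplot2::aes(x = x, y = y),
                       colour = "red") +
    ggplot2::labs(x = "ln |temperature changing rate| (ln degC/s)",
                  y = "nIF (%)",
                  title = sprintf("%s dose-response: %.1f %%/decade",
                                  fit@direction, fit@slopeDecade))
  if (is.finite(fit@baselineNoise)) {
    off <- if (fit@direction == "cooling") fit@baselineNoise
           else -fit@baselineNoise
    g <- g + ggplot2::geom_hline(yintercept = 100 + off, colour = "grey50",
                                 linetype = 2)
  }
  g
}

#' Diagnostic plot of a ST sigmoid fit
#'
#' Mean rate versus temperature with the fitted logistic and the working
#' range. Requires ggplot2.
#'
#' @param temps,rates the per-bin data used for the fit.
#' @param fit a [STFitResult-class].
#' @return a ggplot object.
#' @export
plotSigmoid <- function(temps, rates, fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(temp = temps, rate = rates)
  curveDf <- data.frame(temp = seq(min(temps), max(temps), length.out = 200))
  curveDf$rate <- fit@rateLow + (fit@rateHigh - fit@rateLow) /
    (1 + exp((curveDf$temp - fit@midpointTemp) / fit@width))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = temp, y = rate)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curveDf, colour = "red") +
    ggplot2::labs(x = "temperature (degC)", y = "mean rate (APs/s)",
                  title = sprintf("ST fit: T0 = %.2f degC, %.2f APs/degC",
                                  fit@midpointTemp, fit@slopeAtMidpoint))
  if (is.finite(fit@workingLow))
    g <- g + ggplot2::geom_vline(xintercept = c(fit@workingLow,
                                                fit@workingHigh),
                                 linetype = 2, colour = "grey50")
  g
}
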