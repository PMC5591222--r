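#' Fit a linear CT-contrast calibration curve
#'
#' CT attenuation of a doped casting material is, over the working range,
#' linear in the contrast-agent concentration. This fits the ordinary
#' least-squares line `HU = intercept + slope * concentration` and
#' records the residual RMS and the fitted concentration range, so that
#' target attenuations can be inverted to candidate concentrations.
#'
#' @param concentrations numeric vector (>= 2 distinct values), in
#'   `units`.
#' @param hu_values CT attenuation in Hounsfield units, same length.
#' @param agent label for the contrast agent.
#' @param units concentration units, e.g. `"g/ml"` or `"ml/ml"`.
#' @return An object of class `calibration_curve` with `slope`
#'   (HU per unit concentration), `intercept` (HU), `range`
#'   (fitted concentration range), `rms` (residual RMS, HU), `agent`,
#'   `units`, and the underlying `lm` fit.
#' @examples
#' cal <- fit_curve(c(0, 0.01, 0.02, 0.03), c(10, 110, 210, 310),
#'                  agent = "tantalum", units = "g/ml")
#' target_concentration(cal, 160)
#' @export
fit_curve <- function(concentrations, hu_values, agent = "agent",
                      units = "g/ml") {
  concentrations <- as.numeric(concentrations)
  hu_values <- as.numeric(hu_values)
  if (length(concentrations) != length(hu_values))
    stop("concentrations and hu_values must have equal length")
  if (length(concentrations) < 2) stop("need at least 2 points")
  if (length(unique(concentrations)) < 2)
    stop("concentrations must not be all identical")
  fit <- lm(hu_values ~ concentrations)
  structure(list(agent = agent, units = units,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 range = range(concentrations),
                 rms = sqrt(mean(fit$residuals^2)),
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: %s\n", x$agent))
  cat(sprintf("  HU = %.4g + %.4g * concentration [%s]\n",
              x$intercept, x$slope, x$units))
  cat(sprintf("  fitted range: %.4g .. %.4g %s, residual RMS %.3g HU\n",
              x$range[1], x$range[2], x$units, x$rms))
  invisible(x)
}

#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * as.numeric(concentration)
}

#' Invert a calibration curve for a target attenuation
#'
#' Returns the concentration predicted to achieve `target_hu`, with a
#' warning when the answer lies outside the fitted concentration range
#' (extrapolation beyond the verified linear regime).
#'
#' @param curve a [fit_curve()] result.
#' @param target_hu target attenuation in Hounsfield units.
#' @return Concentration in the curve's units.
#' @export
target_concentration <- function(curve, target_hu) {
  if (isTRUE(all.equal(curve$slope, 0)))
    stop("zero slope: curve cannot be inverted")
  conc <- (as.numeric(target_hu) - curve$intercept) / curve$slope
  if (any(conc < curve$range[1] | conc > curve$range[2]))
    warning("target outside the fitted concentration range (extrapolation)")
  conc
}
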