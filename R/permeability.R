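#' @include AllGenerics.R
NULL

#' Fit a fluorescence calibration line
#'
#' Ordinary least squares of fluorescence on concentration after averaging
#' duplicate readings per dilution point. The fitted gain must be positive:
#' a flat dilution series carries no calibration information.
#'
#' @param concentrations mol/L, one per reading (duplicate concentrations
#'   allowed and expected).
#' @param readings fluorescence, a.u., same length.
#' @return A [CalibrationCurve-class].
#' @examples
#' conc <- rep(c(1e-8, 1e-7, 1e-6), each = 2)
#' fitCalibration(conc, 2e9 * conc + c(-1, 1))
#' @export
fitCalibration <- function(concentrations, readings) {
  if (length(concentrations) != length(readings))
    stop("concentrations and readings must have equal length", call. = FALSE)
  agg <- tapply(readings, concentrations, mean)
  conc <- as.numeric(names(agg))
  fl <- as.numeric(agg)
  if (length(conc) < 3L)
    stop("at least 3 distinct dilution points are required", call. = FALSE)
  if (stats::var(conc) == 0)
    stop("concentrations have zero variance", call. = FALSE)
  fit <- stats::lm(fl ~ conc)
  gain <- unname(stats::coef(fit)[2])
  if (!is.finite(gain) || gain <= 0)
    stop("fitted gain is not positive (", format(gain), "); the dilution ",
         "series carries no signal", call. = FALSE)
  ssTot <- sum((fl - mean(fl))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else NA_real_
  new("CalibrationCurve", concentrations = conc, fluorescence = fl,
      gain = gain, intercept = unname(stats::coef(fit)[1]), r2 = r2)
}

#' Flux and permeability from a tracer accumulation series
#'
#' Converts timed basolateral samples into a flux J and an apparent
#' permeability P = J/dc. Raw fluorescence is first mapped to concentration
#' through the calibration line and then to amount via the basolateral
#' volume; amount vs time is fitted by ordinary least squares, and the slope
#' (mol/min) becomes \deqn{J = slope \cdot 60 / area \quad [mol\,h^{-1}cm^{-2}],}
#' \deqn{P = \frac{J / 3600}{\Delta c \cdot 10^{-3}} \quad [cm\,s^{-1}],}
#' where \eqn{\Delta c} in mol/L is converted to mol/cm3 (the factor 1e-3)
#' so that P comes out in cm/s. A sink condition is assumed (basolateral
#' concentration negligible against apical over the sampling hour).
#'
#' @param series a [FluxSeries-class] carrying either fluorescence (then
#'   \code{calib} is required) or amounts.
#' @param calib a [CalibrationCurve-class], required for fluorescence input.
#' @param skipFirst drop the first sample (lag-phase handling); off by
#'   default, matching slope-through-origin-inclusive practice.
#' @param negTol flag the result when the fitted slope is more negative than
#'   \code{-negTol} times its standard error.
#' @param ... unused.
#' @return A [PermeabilityResult-class].
#' @examples
#' fs <- FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
#'                  amounts = c(0, 0.5, 1, 1.5, 2), amountUnit = "nmol",
#'                  apicalConc = 1e-4, area = 0.049)
#' fluxFromSeries(fs)  # J = 4.08e-8 mol/h/cm2, P = 1.134e-4 cm/s
#' @export
setMethod("fluxFromSeries", "FluxSeries",
  function(series, calib = NULL, skipFirst = FALSE, negTol = 2, ...) {
    t <- series@times
    if (length(series@amounts)) {
      amount <- series@amounts * if (series@amountUnit == "nmol") 1e-9 else 1
    } else {
      if (is.null(calib))
        stop("a CalibrationCurve is required to convert fluorescence ",
             "readings", call. = FALSE)
      conc <- (series@fluorescence - calib@intercept) / calib@gain  # mol/L
      amount <- conc * series@volumeMl / 1000                        # mol
    }
    if (skipFirst) {
      t <- t[-1]
      amount <- amount[-1]
    }
    if (length(t) < 3L)
      stop("at least 3 samples are required to fit an appearance rate",
           call. = FALSE)
    fit <- stats::lm(amount ~ t)
    slope <- unname(stats::coef(fit)[2])            # mol/min
    # slope SE computed directly (summary.lm warns on exact fits)
    se <- sqrt(sum(stats::residuals(fit)^2) / (length(t) - 2)) /
      sqrt(sum((t - mean(t))^2))
    flags <- character()
    if (is.finite(se) && se > 0 && slope < -negTol * se)
      flags <- "negative-slope"
    ssTot <- sum((amount - mean(amount))^2)
    r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else NA_real_
    J <- slope * 60 / series@area                    # mol/h/cm2
    P <- J / 3600 / (series@apicalConc * 1e-3)       # cm/s
    new("PermeabilityResult", J = J, P = P, r2 = r2,
        nPoints = length(t), flags = flags)
  })
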