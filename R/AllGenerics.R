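#' @include AllClasses.R
NULL

#' @rdname fitOnePath
#' @export
setGeneric("fitOnePath", function(spec, init = NULL,
                                  method = c("fit", "intercept"), ...)
  standardGeneric("fitOnePath"))

#' @rdname correctBathResistance
#' @export
setGeneric("correctBathResistance", function(spec, rBath)
  standardGeneric("correctBathResistance"))

#' @rdname baselineIsc
#' @export
setGeneric("baselineIsc", function(trace, ...) standardGeneric("baselineIsc"))

#' @rdname bumetanideResponse
#' @export
setGeneric("bumetanideResponse", function(trace, ...)
  standardGeneric("bumetanideResponse"))

#' @rdname amilorideJNa
#' @export
setGeneric("amilorideJNa", function(trace, ...)
  standardGeneric("amilorideJNa"))

#' @rdname fluxFromSeries
#' @export
setGeneric("fluxFromSeries", function(series, calib = NULL, ...)
  standardGeneric("fluxFromSeries"))

#' @rdname ttjBtjRatio
#' @export
setGeneric("ttjBtjRatio", function(profile, ...)
  standardGeneric("ttjBtjRatio"))

# ---- accessors ----

#' Accessors for fitted circuit parameters and results
#'
#' \code{rSub}, \code{rEpi}, \code{rT} and \code{capacitance} extract the
#' subepithelial, epithelial and transmural resistances (Ohm.cm2) and the
#' epithelial capacitance (F/cm2) from a [OnePathFit-class]. \code{converged}
#' and \code{residualNorm} expose the fit diagnostics. \code{deltaIsc}
#' extracts the signed current change from a [DrugResponse-class].
#' \code{permeability} and \code{flux} extract P (cm/s) and J (mol/h/cm2)
#' from a [PermeabilityResult-class]. \code{subjectMean} extracts the flat
#' per-subject mean from a [TricellularRatio-class].
#'
#' @param object the object to extract from.
#' @return A numeric (or logical, for \code{converged}) scalar.
#' @name accessors
#' @aliases rSub rEpi rT capacitance converged residualNorm deltaIsc
#'   permeability flux subjectMean
NULL

#' @rdname accessors
#' @export
setGeneric("rSub", function(object) standardGeneric("rSub"))
#' @rdname accessors
#' @export
setGeneric("rEpi", function(object) standardGeneric("rEpi"))
#' @rdname accessors
#' @export
setGeneric("rT", function(object) standardGeneric("rT"))
#' @rdname accessors
#' @export
setGeneric("capacitance", function(object) standardGeneric("capacitance"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))
#' @rdname accessors
#' @export
setGeneric("deltaIsc", function(object) standardGeneric("deltaIsc"))
#' @rdname accessors
#' @export
setGeneric("permeability", function(object) standardGeneric("permeability"))
#' @rdname accessors
#' @export
setGeneric("flux", function(object) standardGeneric("flux"))
#' @rdname accessors
#' @export
setGeneric("subjectMean", function(object) standardGeneric("subjectMean"))

#' @rdname accessors
setMethod("rSub", "OnePathFit", function(object) object@rSub)
#' @rdname accessors
setMethod("rEpi", "OnePathFit", function(object) object@rEpi)
#' @rdname accessors
setMethod("rT", "OnePathFit", function(object) object@rT)
#' @rdname accessors
setMethod("capacitance", "OnePathFit", function(object) object@cap)
#' @rdname accessors
setMethod("converged", "OnePathFit", function(object) object@converged)
#' @rdname accessors
setMethod("residualNorm", "OnePathFit", function(object) object@residualNorm)
#' @rdname accessors
setMethod("deltaIsc", "DrugResponse", function(object) object@deltaIsc)
#' @rdname accessors
setMethod("permeability", "PermeabilityResult", function(object) object@P)
#' @rdname accessors
setMethod("flux", "PermeabilityResult", function(object) object@J)
#' @rdname accessors
setMethod("subjectMean", "TricellularRatio", function(object) object@subjectMean)

# ---- show methods ----

setMethod("show", "ImpedanceSpectrum", function(object) {
  cat("ImpedanceSpectrum:", length(object@freqs), "frequencies,",
      format(min(object@freqs), digits = 3), "-",
      format(max(object@freqs), digits = 3), "Hz;",
      if (object@bathCorrected) "bath-corrected" else "uncorrected", "\n")
})

setMethod("show", "OnePathFit", function(object) {
  cat(sprintf(
    "OnePathFit (%s): rSub = %.3g, rEpi = %.3g, rT = %.3g Ohm.cm2, cap = %.3g uF/cm2\n  residual norm %.3g, %s\n",
    object@method, object@rSub, object@rEpi, object@rT, object@cap * 1e6,
    object@residualNorm,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "IscTrace", function(object) {
  cat("IscTrace:", length(object@time), "samples over",
      format(diff(range(object@time)), digits = 4), "min;",
      nrow(object@events), "drug event(s)\n")
  if (nrow(object@events))
    cat("  drugs:", paste(object@events$drug, collapse = ", "), "\n")
})

setMethod("show", "DrugResponse", function(object) {
  cat(sprintf("DrugResponse [%s]: deltaIsc = %.4g uA/cm2 (pre %.4g, post %.4g)\n",
              object@drug, object@deltaIsc, object@preValue, object@postValue))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: gain = %.4g a.u. per mol/L, intercept = %.4g, r2 = %.5f (%d points)\n",
              object@gain, object@intercept, object@r2,
              length(object@concentrations)))
})

setMethod("show", "FluxSeries", function(object) {
  cat(sprintf("FluxSeries [%s, %g Da]: %d samples to %g min; apical %g mol/L, area %g cm2\n",
              object@tracer, object@molarMass, length(object@times),
              max(object@times), object@apicalConc, object@area))
})

setMethod("show", "PermeabilityResult", function(object) {
  cat(sprintf("PermeabilityResult: J = %.4g mol/h/cm2, P = %.4g cm/s (r2 = %.4f, n = %d)\n",
              object@J, object@P, object@r2, as.integer(object@nPoints)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d samples over %.3g um, tTJ anchor at %.3g um\n",
              length(object@positions), diff(range(object@positions)),
              object@ttjAnchor))
})

setMethod("show", "TricellularRatio", function(object) {
  cat(sprintf("TricellularRatio [%s]: subject mean %.4g over %d measurements in %d section(s)\n",
              object@subjectId, object@subjectMean,
              as.integer(object@nMeasurements), length(object@sectionMeans)))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d control vs %d IBS-M subjects, seed %d\n",
              object@nControl, object@nIbsm, object@seed))
  cat("  parameters:", paste(names(object@control), collapse = ", "), "\n")
})
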