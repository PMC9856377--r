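#' @import methods
NULL

#' Impedance spectrum of one specimen
#'
#' Complex transepithelial impedance sampled at a set of frequencies for a
#' single tissue specimen mounted in an Ussing chamber. Frequencies are in Hz
#' (sorted ascending), impedances in Ohm.cm2. The \code{bathCorrected} flag
#' records whether the series resistance of the bathing solution has already
#' been subtracted from the real part.
#'
#' @slot freqs numeric, frequencies in Hz, strictly increasing.
#' @slot z complex impedance values, Ohm.cm2, one per frequency.
#' @slot bathCorrected logical flag.
#' @slot specimenId character identifier.
#'
#' @seealso [simulateImpedanceSpectrum()], [fitOnePath()],
#'   [correctBathResistance()]
#' @export
setClass("ImpedanceSpectrum",
  representation(freqs = "numeric", z = "complex",
                 bathCorrected = "logical", specimenId = "character"),
  prototype(bathCorrected = FALSE, specimenId = NA_character_),
  validity = function(object) {
    msg <- character()
    if (length(object@freqs) < 1L)
      msg <- c(msg, "at least one frequency is required")
    if (length(object@freqs) != length(object@z))
      msg <- c(msg, "freqs and z must have equal length")
    if (any(!is.finite(object@freqs)) || any(object@freqs <= 0))
      msg <- c(msg, "frequencies must be finite and > 0")
    if (length(object@freqs) > 1L && any(diff(object@freqs) <= 0))
      msg <- c(msg, "frequencies must be strictly increasing")
    if (any(!is.finite(Re(object@z))) || any(!is.finite(Im(object@z))))
      msg <- c(msg, "impedance values must be finite")
    if (length(object@bathCorrected) != 1L)
      msg <- c(msg, "bathCorrected must be a single flag")
    if (length(msg)) msg else TRUE
  })

#' Constructor for [ImpedanceSpectrum-class]
#'
#' @param freqs frequencies in Hz, strictly increasing.
#' @param z complex impedances, Ohm.cm2.
#' @param bathCorrected has the bath resistance already been subtracted?
#' @param specimenId specimen identifier.
#' @return An [ImpedanceSpectrum-class] object.
#' @examples
#' f <- defaultFrequencyGrid()
#' z <- onePathImpedance(12, 25, 3e-6, f)
#' ImpedanceSpectrum(f, z, bathCorrected = TRUE)
#' @export
ImpedanceSpectrum <- function(freqs, z, bathCorrected = FALSE,
                              specimenId = NA_character_) {
  new("ImpedanceSpectrum", freqs = as.numeric(freqs), z = as.complex(z),
      bathCorrected = isTRUE(bathCorrected),
      specimenId = as.character(specimenId))
}

#' One-path equivalent-circuit fit
#'
#' Result of fitting the lumped one-path RC model to an impedance spectrum:
#' a series subepithelial resistor \code{rSub} plus a parallel RC element
#' (\code{rEpi}, \code{cap}) for the epithelium. \code{rT} is stored as the
#' exact sum \code{rSub + rEpi}.
#'
#' @slot rSub subepithelial resistance, Ohm.cm2.
#' @slot rEpi epithelial resistance, Ohm.cm2.
#' @slot rT transmural resistance, Ohm.cm2 (= rSub + rEpi).
#' @slot cap epithelial capacitance, F/cm2.
#' @slot residualNorm Euclidean norm of the stacked (Re, Im) residuals.
#' @slot converged logical convergence flag.
#' @slot method "fit" (full complex least squares) or "intercept".
#' @slot specimenId character identifier.
#' @export
setClass("OnePathFit",
  representation(rSub = "numeric", rEpi = "numeric", rT = "numeric",
                 cap = "numeric", residualNorm = "numeric",
                 converged = "logical", method = "character",
                 specimenId = "character"),
  validity = function(object) {
    msg <- character()
    if (object@rSub <= 0) msg <- c(msg, "rSub must be > 0")
    if (object@rEpi < 0) msg <- c(msg, "rEpi must be >= 0")
    if (object@cap <= 0) msg <- c(msg, "cap must be > 0")
    if (abs(object@rT - (object@rSub + object@rEpi)) >
        1e-9 * max(1, object@rT))
      msg <- c(msg, "rT must equal rSub + rEpi")
    if (length(msg)) msg else TRUE
  })

.OnePathFit <- function(rSub, rEpi, cap, residualNorm, converged, method,
                        specimenId = NA_character_) {
  new("OnePathFit", rSub = rSub, rEpi = rEpi, rT = rSub + rEpi, cap = cap,
      residualNorm = residualNorm, converged = converged, method = method,
      specimenId = as.character(specimenId))
}

#' Short-circuit current trace
#'
#' A sampled short-circuit current (Isc) time course with timed drug-addition
#' events. Times in minutes (strictly increasing), currents in uA/cm2. Events
#' are a data.frame with columns \code{drug}, \code{time_min}, \code{side}
#' ("mucosal" or "serosal"); at most one event per drug.
#'
#' @slot time numeric, minutes.
#' @slot isc numeric, uA/cm2.
#' @slot events data.frame of drug additions.
#' @slot specimenId character identifier.
#' @seealso [baselineIsc()], [bumetanideResponse()], [amilorideJNa()]
#' @export
setClass("IscTrace",
  representation(time = "numeric", isc = "numeric", events = "data.frame",
                 specimenId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@isc))
      msg <- c(msg, "time and isc must have equal length")
    if (length(object@time) && any(diff(object@time) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    ev <- object@events
    need <- c("drug", "time_min", "side")
    if (!all(need %in% names(ev)))
      msg <- c(msg, "events must have columns drug, time_min, side")
    else if (anyDuplicated(ev$drug))
      msg <- c(msg, "at most one event per drug")
    if (length(msg)) msg else TRUE
  })

#' Constructor for [IscTrace-class]
#'
#' @param time sample times, minutes, strictly increasing.
#' @param isc short-circuit current, uA/cm2.
#' @param events data.frame with columns \code{drug}, \code{time_min},
#'   \code{side}; see [drugEvents()].
#' @param specimenId specimen identifier.
#' @return An [IscTrace-class] object.
#' @export
IscTrace <- function(time, isc, events = drugEvents(), specimenId = NA_character_) {
  new("IscTrace", time = as.numeric(time), isc = as.numeric(isc),
      events = events, specimenId = as.character(specimenId))
}

#' Build a drug-event table
#'
#' @param drug character vector of drug names.
#' @param time_min addition times in minutes.
#' @param side "mucosal" or "serosal" per event.
#' @return data.frame with one row per event.
#' @examples
#' drugEvents("bumetanide", 15, "serosal")
#' @export
drugEvents <- function(drug = character(), time_min = numeric(),
                       side = character()) {
  if (length(side) == 0L && length(drug) > 0L) side <- rep("serosal", length(drug))
  data.frame(drug = as.character(drug), time_min = as.numeric(time_min),
             side = as.character(side), stringsAsFactors = FALSE)
}

#' Quantified drug response
#'
#' A signed change in short-circuit current attributed to one drug addition.
#' The invariant \code{deltaIsc == preValue - postValue} holds exactly by
#' construction.
#'
#' @slot drug drug name.
#' @slot deltaIsc signed Isc change, uA/cm2.
#' @slot preValue pre-drug reference value, uA/cm2.
#' @slot postValue post-drug value, uA/cm2.
#' @slot window numeric length-2, the post-drug read-out window (min).
#' @slot flags character vector of quality flags (e.g. "negative-response").
#' @export
setClass("DrugResponse",
  representation(drug = "character", deltaIsc = "numeric",
                 preValue = "numeric", postValue = "numeric",
                 window = "numeric", flags = "character"),
  validity = function(object) {
    if (abs(object@deltaIsc - (object@preValue - object@postValue)) >
        1e-12 * max(1, abs(object@preValue)))
      "deltaIsc must equal preValue - postValue" else TRUE
  })

.DrugResponse <- function(drug, preValue, postValue, window,
                          flags = character()) {
  new("DrugResponse", drug = drug, deltaIsc = preValue - postValue,
      preValue = preValue, postValue = postValue, window = window,
      flags = flags)
}

#' Fluorescence calibration curve
#'
#' Ordinary least-squares line relating fluorescence (a.u.) to tracer
#' concentration (mol/L), fitted on duplicate-averaged readings from a
#' dilution series.
#'
#' @slot concentrations mol/L, distinct dilution points.
#' @slot fluorescence duplicate-averaged readings, a.u.
#' @slot gain fitted slope, a.u. per mol/L (> 0).
#' @slot intercept fitted intercept, a.u.
#' @slot r2 coefficient of determination of the line.
#' @export
setClass("CalibrationCurve",
  representation(concentrations = "numeric", fluorescence = "numeric",
                 gain = "numeric", intercept = "numeric", r2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@concentrations) < 3L)
      msg <- c(msg, "at least 3 dilution points are required")
    if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Timed basolateral tracer accumulation series
#'
#' Appearance of an apically added tracer in the basolateral compartment,
#' recorded either as raw fluorescence (to be converted via a
#' [CalibrationCurve-class]) or directly as amounts. Geometry and driving
#' concentration travel with the series so the permeability computation is
#' self-contained.
#'
#' @slot tracer tracer name ("fluorescein", "fd4", ...).
#' @slot molarMass Da (fluorescein 332, FITC-dextran-4000 4000).
#' @slot times sample times, minutes, increasing from 0.
#' @slot fluorescence raw basolateral readings, a.u. (may be empty).
#' @slot amounts basolateral amounts (in \code{amountUnit}; may be empty).
#' @slot amountUnit "mol" or "nmol".
#' @slot apicalConc driving concentration difference, mol/L.
#' @slot area exposed tissue area, cm2 (0.049 for the miniaturized chamber).
#' @slot volumeMl basolateral chamber volume, mL.
#' @export
setClass("FluxSeries",
  representation(tracer = "character", molarMass = "numeric",
                 times = "numeric", fluorescence = "numeric",
                 amounts = "numeric", amountUnit = "character",
                 apicalConc = "numeric", area = "numeric",
                 volumeMl = "numeric"),
  prototype(amountUnit = "mol"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) && any(diff(object@times) <= 0))
      msg <- c(msg, "sample times must be strictly increasing")
    if (length(object@times) && object@times[1] < 0)
      msg <- c(msg, "sample times must start at or after 0")
    n <- length(object@times)
    if (length(object@fluorescence) && length(object@fluorescence) != n)
      msg <- c(msg, "fluorescence length must match times")
    if (length(object@amounts) && length(object@amounts) != n)
      msg <- c(msg, "amounts length must match times")
    if (!length(object@fluorescence) && !length(object@amounts))
      msg <- c(msg, "either fluorescence or amounts must be present")
    if (object@apicalConc <= 0) msg <- c(msg, "apicalConc must be > 0")
    if (object@area <= 0) msg <- c(msg, "area must be > 0")
    if (object@volumeMl <= 0) msg <- c(msg, "volumeMl must be > 0")
    if (!object@amountUnit %in% c("mol", "nmol"))
      msg <- c(msg, "amountUnit must be 'mol' or 'nmol'")
    if (length(msg)) msg else TRUE
  })

#' Constructor for [FluxSeries-class]
#'
#' @param tracer tracer name.
#' @param times sample times, minutes.
#' @param fluorescence raw readings (a.u.), or NULL.
#' @param amounts basolateral amounts, or NULL.
#' @param apicalConc apical tracer concentration, mol/L.
#' @param area exposed area, cm2.
#' @param volumeMl basolateral volume, mL.
#' @param amountUnit unit of \code{amounts}, "mol" or "nmol".
#' @param molarMass tracer molar mass, Da.
#' @return A [FluxSeries-class] object.
#' @export
FluxSeries <- function(tracer, times, fluorescence = NULL, amounts = NULL,
                       apicalConc, area = 0.049, volumeMl = 1,
                       amountUnit = "mol",
                       molarMass = if (identical(tracer, "fluorescein")) 332 else 4000) {
  new("FluxSeries", tracer = as.character(tracer), molarMass = molarMass,
      times = as.numeric(times),
      fluorescence = as.numeric(fluorescence %||% numeric()),
      amounts = as.numeric(amounts %||% numeric()),
      amountUnit = amountUnit, apicalConc = apicalConc, area = area,
      volumeMl = volumeMl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flux and permeability result
#'
#' @slot J flux, mol/h/cm2.
#' @slot P apparent permeability, cm/s; exactly
#'   \code{J / 3600 / (apicalConc * 1e-3)}.
#' @slot r2 coefficient of determination of the amount-vs-time line.
#' @slot nPoints number of samples used.
#' @slot flags quality flags (e.g. "negative-slope").
#' @export
setClass("PermeabilityResult",
  representation(J = "numeric", P = "numeric", r2 = "numeric",
                 nPoints = "numeric", flags = "character"))

#' Junctional intensity line profile
#'
#' A 1-D fluorescence intensity profile sampled uniformly along an epithelial
#' tight junction, with the tricellular meeting point (tTJ) marked as an
#' anchor position.
#'
#' @slot positions um, uniformly spaced.
#' @slot intensities a.u., background-positive.
#' @slot ttjAnchor anchor position, um.
#' @slot sectionId tissue-section identifier.
#' @slot subjectId subject identifier.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", intensities = "numeric",
                 ttjAnchor = "numeric", sectionId = "character",
                 subjectId = "character"),
  prototype(sectionId = NA_character_, subjectId = NA_character_),
  validity = function(object) {
    msg <- character()
    if (length(object@positions) != length(object@intensities))
      msg <- c(msg, "positions and intensities must have equal length")
    if (length(object@positions) >= 3L) {
      dp <- diff(object@positions)
      if (max(dp) - min(dp) > 1e-6)
        msg <- c(msg, "sampling must be uniform (within 1e-6 um)")
    }
    a <- object@ttjAnchor
    p <- object@positions
    if (length(p)) {
      if (a < min(p) || a > max(p))
        msg <- c(msg, "anchor must lie inside the profile")
      else if ((max(p) - a) < 2 && (a - min(p)) < 2)
        msg <- c(msg, "anchor needs >= 2 um of profile on at least one side")
    }
    if (length(msg)) msg else TRUE
  })

#' Constructor for [IntensityProfile-class]
#'
#' @param positions um, uniformly spaced.
#' @param intensities a.u.
#' @param ttjAnchor tricellular anchor position, um.
#' @param sectionId,subjectId identifiers.
#' @return An [IntensityProfile-class] object.
#' @export
IntensityProfile <- function(positions, intensities, ttjAnchor,
                             sectionId = NA_character_,
                             subjectId = NA_character_) {
  new("IntensityProfile", positions = as.numeric(positions),
      intensities = as.numeric(intensities), ttjAnchor = ttjAnchor,
      sectionId = as.character(sectionId), subjectId = as.character(subjectId))
}

#' Aggregated tricellular/bicellular intensity ratios for one subject
#'
#' @slot ratios per-measurement tTJ/bTJ ratios.
#' @slot sections section id per measurement.
#' @slot sectionMeans named per-section mean ratios.
#' @slot subjectMean flat mean over all measurements (default aggregation).
#' @slot subjectMeanBySection mean of the per-section means.
#' @slot nMeasurements number of measurements.
#' @slot subjectId subject identifier.
#' @export
setClass("TricellularRatio",
  representation(ratios = "numeric", sections = "character",
                 sectionMeans = "numeric", subjectMean = "numeric",
                 subjectMeanBySection = "numeric", nMeasurements = "numeric",
                 subjectId = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@ratios <= 0)) msg <- c(msg, "ratios must be > 0")
    if (length(object@ratios) &&
        abs(object@subjectMean - mean(object@ratios)) > 1e-12 * max(1, object@subjectMean))
      msg <- c(msg, "subjectMean must be the flat mean of the ratios")
    if (length(msg)) msg else TRUE
  })

#' Synthetic cohort configuration
#'
#' Group sizes, per-modality ground-truth parameter blocks (mean and SD per
#' group) and noise levels for the synthetic cohort generator. Parameter
#' blocks are named lists of \code{c(mean, sd)} pairs; see
#' [defaultCohortConfig()] for the packaged defaults mirroring the printed
#' group summaries of the study population.
#'
#' @slot nControl number of control subjects (>= 1).
#' @slot nIbsm number of IBS-M subjects (>= 1).
#' @slot control named list of \code{c(mean, sd)} parameter entries.
#' @slot ibsm named list, same names as \code{control}.
#' @slot noise named list of measurement-noise levels.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(nControl = "integer", nIbsm = "integer",
                 control = "list", ibsm = "list", noise = "list",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nControl < 1L || object@nIbsm < 1L)
      msg <- c(msg, "group sizes must be >= 1")
    if (!identical(sort(names(object@control)), sort(names(object@ibsm))))
      msg <- c(msg, "control and ibsm blocks must share parameter names")
    for (grp in list(object@control, object@ibsm)) {
      for (nm in names(grp)) {
        v <- grp[[nm]]
        if (length(v) != 2L || any(!is.finite(v)))
          msg <- c(msg, paste0("parameter '", nm, "' must be c(mean, sd)"))
        else if (v[2] < 0)
          msg <- c(msg, paste0("SD of '", nm, "' must be >= 0"))
      }
    }
    for (grp in list(object@control, object@ibsm)) {
      for (nm in c("rEpi", "rSub", "capUF"))
        if (!is.null(grp[[nm]]) && grp[[nm]][1] <= 0)
          msg <- c(msg, paste0("mean of '", nm, "' must be > 0"))
      af <- grp[["apoptosisFraction"]]
      if (!is.null(af) && (af[1] < 0 || af[1] > 1))
        msg <- c(msg, "apoptosisFraction mean must be in [0, 1]")
      en <- grp[["ttjEnrichment"]]
      if (!is.null(en) && en[1] < 1)
        msg <- c(msg, "ttjEnrichment mean must be >= 1")
    }
    if (length(msg)) unique(msg) else TRUE
  })
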