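# Synthetic-data generators. Each generator takes explicit ground-truth
# parameters plus a noise level and a seed, so every analysis operation has
# a known-truth round-trip partner. noiseSd = 0 always yields the exact
# model curve.

#' Simulate an impedance spectrum
#'
#' Evaluates the one-path circuit model [onePathImpedance()] on a frequency
#' grid and applies independent multiplicative Gaussian perturbations of
#' relative magnitude \code{noiseSd} to the real and imaginary parts.
#'
#' @param rSub,rEpi,cap circuit ground truth (Ohm.cm2, Ohm.cm2, F/cm2; all
#'   > 0).
#' @param freqs frequency grid, Hz (default: 48 log-spaced points,
#'   1.3 Hz-65 kHz).
#' @param noiseSd relative noise fraction (0 = exact model curve).
#' @param seed RNG seed (NULL = ambient RNG).
#' @param specimenId identifier.
#' @return An [ImpedanceSpectrum-class] with \code{bathCorrected = TRUE}
#'   (no bath term is simulated).
#' @export
simulateImpedanceSpectrum <- function(rSub, rEpi, cap,
                                      freqs = defaultFrequencyGrid(),
                                      noiseSd = 0, seed = NULL,
                                      specimenId = NA_character_) {
  .assertScalar(rSub, "rSub", positive = TRUE)
  .assertScalar(rEpi, "rEpi", positive = TRUE)
  .assertScalar(cap, "cap", positive = TRUE)
  .assertScalar(noiseSd, "noiseSd", nonNegative = TRUE)
  if (!length(freqs)) stop("frequency list is empty", call. = FALSE)
  .assertIncreasing(freqs, "freqs")
  if (any(freqs <= 0)) stop("frequencies must be > 0", call. = FALSE)
  z <- onePathImpedance(rSub, rEpi, cap, freqs)
  .withSeed(seed, {
    re <- Re(z) * (1 + stats::rnorm(length(z), 0, noiseSd))
    im <- Im(z) * (1 + stats::rnorm(length(z), 0, noiseSd))
    ImpedanceSpectrum(freqs, complex(real = re, imaginary = im),
                      bathCorrected = TRUE, specimenId = specimenId)
  })
}

#' Simulate a short-circuit current trace
#'
#' Constant baseline current with first-order (exponential) approaches to a
#' post-drug plateau for each event: after an addition at \eqn{t_0} with
#' effect \eqn{E} and rate constant \eqn{k},
#' \eqn{Isc(t) = baseline - E(1 - e^{-k(t - t_0)})} for \eqn{t \ge t_0}
#' (effects of multiple events add). Additive Gaussian noise in uA/cm2.
#'
#' @param baseline baseline Isc, uA/cm2.
#' @param events data.frame with columns \code{drug}, \code{time_min},
#'   \code{effect} (uA/cm2), \code{rate} (1/min, >= 0) and optionally
#'   \code{side}; NULL for an event-free trace.
#' @param duration trace length, minutes (> 0).
#' @param dt sampling interval, minutes.
#' @param noiseSd additive noise SD, uA/cm2.
#' @param seed RNG seed.
#' @param specimenId identifier.
#' @return An [IscTrace-class] (events table keeps drug/time/side only).
#' @export
simulateIscTrace <- function(baseline, events = NULL, duration = 45,
                             dt = 0.5, noiseSd = 0, seed = NULL,
                             specimenId = NA_character_) {
  .assertScalar(baseline, "baseline")
  .assertScalar(duration, "duration", positive = TRUE)
  .assertScalar(dt, "dt", positive = TRUE)
  .assertScalar(noiseSd, "noiseSd", nonNegative = TRUE)
  time <- seq(0, duration, by = dt)
  isc <- rep(baseline, length(time))
  if (!is.null(events) && nrow(events)) {
    if (!all(c("drug", "time_min", "effect", "rate") %in% names(events)))
      stop("events needs columns drug, time_min, effect, rate", call. = FALSE)
    if (any(events$rate < 0))
      stop("rate constants must be >= 0", call. = FALSE)
    if (any(events$time_min < 0 | events$time_min > duration))
      stop("event times must lie within the trace duration", call. = FALSE)
    for (i in seq_len(nrow(events))) {
      after <- time >= events$time_min[i]
      isc[after] <- isc[after] - events$effect[i] *
        (1 - exp(-events$rate[i] * (time[after] - events$time_min[i])))
    }
  }
  evTable <- if (is.null(events) || !nrow(events)) drugEvents() else
    drugEvents(events$drug, events$time_min,
               if ("side" %in% names(events)) events$side else
                 rep("serosal", nrow(events)))
  .withSeed(seed, {
    isc <- isc + stats::rnorm(length(isc), 0, noiseSd)
    IscTrace(time, isc, evTable, specimenId = specimenId)
  })
}

#' Simulate a tracer flux series with its calibration dilution series
#'
#' Under the sink condition the basolateral amount grows linearly:
#' \eqn{amount(t) = P \cdot \Delta c \cdot area \cdot t} with \eqn{\Delta c}
#' converted to mol/cm3 and \eqn{t} to seconds. The amounts are rendered as
#' fluorescence readings through a linear gain (plus background intercept),
#' and a matching calibration dilution series with duplicate readings is
#' generated with the same gain. Relative Gaussian noise is applied to all
#' fluorescence readings.
#'
#' @param perm ground-truth permeability, cm/s (>= 0).
#' @param apicalConc apical tracer concentration, mol/L.
#' @param area exposed tissue area, cm2.
#' @param volumeMl basolateral chamber volume, mL.
#' @param sampleTimes minutes, increasing from 0.
#' @param noiseSd relative fluorescence noise fraction.
#' @param seed RNG seed.
#' @param tracer tracer name ("fluorescein" 100 uM or "fd4" 0.4 mM by
#'   convention).
#' @param gain fluorescence gain, a.u. per mol/L.
#' @param background fluorescence intercept, a.u.
#' @param calibConcs calibration dilution concentrations, mol/L.
#' @return List with elements \code{series} (a [FluxSeries-class] carrying
#'   fluorescence) and \code{calibration} (data.frame \code{conc_mol_l},
#'   \code{fluorescence} with duplicate rows per dilution).
#' @export
simulateFluxSeries <- function(perm, apicalConc = 1e-4, area = 0.049,
                               volumeMl = 1,
                               sampleTimes = c(0, 15, 30, 45, 60),
                               noiseSd = 0, seed = NULL,
                               tracer = "fluorescein", gain = 1e9,
                               background = 20,
                               calibConcs = apicalConc *
                                 c(0, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3)) {
  .assertScalar(perm, "perm", nonNegative = TRUE)
  .assertScalar(apicalConc, "apicalConc", positive = TRUE)
  .assertScalar(area, "area", positive = TRUE)
  .assertScalar(volumeMl, "volumeMl", positive = TRUE)
  .assertIncreasing(sampleTimes, "sampleTimes")
  if (sampleTimes[1] < 0)
    stop("sample times must increase from 0", call. = FALSE)
  amounts <- perm * (apicalConc * 1e-3) * area * (sampleTimes * 60)  # mol
  conc <- amounts / (volumeMl / 1000)                                # mol/L
  .withSeed(seed, {
    fl <- (gain * conc + background) *
      (1 + stats::rnorm(length(conc), 0, noiseSd))
    calConc <- rep(calibConcs, each = 2)
    calFl <- (gain * calConc + background) *
      (1 + stats::rnorm(length(calConc), 0, noiseSd))
    list(
      series = FluxSeries(tracer, sampleTimes, fluorescence = fl,
                          apicalConc = apicalConc, area = area,
                          volumeMl = volumeMl),
      calibration = data.frame(conc_mol_l = calConc, fluorescence = calFl))
  })
}

#' Simulate a junctional intensity line profile
#'
#' Flat background with a Gaussian peak of amplitude
#' \eqn{(enrichment - 1) \cdot background} centred on the tricellular
#' anchor: \code{enrichment = 1} is a fully delocalized (flat) profile,
#' larger values reproduce control-like tTJ concentration. Multiplicative
#' Gaussian noise. A warning is issued when the sampling step is coarser
#' than the peak width (the ratio estimate degrades).
#'
#' @param lengthUm profile length, um.
#' @param samplingUm sampling step, um.
#' @param ttjPosition anchor position, um (default: profile centre).
#' @param enrichment ground-truth tTJ/bTJ ratio (>= 1... values below 1 are
#'   rejected; 1 = full delocalization).
#' @param peakWidthUm Gaussian sigma of the tTJ peak, um.
#' @param background background intensity, a.u. (> 0).
#' @param noiseSd relative noise fraction.
#' @param seed RNG seed.
#' @param sectionId,subjectId identifiers.
#' @return An [IntensityProfile-class].
#' @export
simulateIntensityProfile <- function(lengthUm = 20, samplingUm = 0.25,
                                     ttjPosition = lengthUm / 2,
                                     enrichment = 2.5, peakWidthUm = 0.5,
                                     background = 100, noiseSd = 0,
                                     seed = NULL,
                                     sectionId = NA_character_,
                                     subjectId = NA_character_) {
  .assertScalar(enrichment, "enrichment")
  if (enrichment < 1)
    stop("enrichment must be >= 1 (1 = fully delocalized)", call. = FALSE)
  .assertScalar(background, "background", positive = TRUE)
  .assertScalar(peakWidthUm, "peakWidthUm", positive = TRUE)
  if (samplingUm > peakWidthUm)
    warning("sampling step (", samplingUm, " um) is coarser than the peak ",
            "width (", peakWidthUm, " um); ratio estimates will degrade")
  pos <- seq(0, lengthUm, by = samplingUm)
  int <- background *
    (1 + (enrichment - 1) * exp(-(pos - ttjPosition)^2 / (2 * peakWidthUm^2)))
  .withSeed(seed, {
    int <- int * (1 + stats::rnorm(length(int), 0, noiseSd))
    IntensityProfile(pos, int, ttjAnchor = ttjPosition,
                     sectionId = sectionId, subjectId = subjectId)
  })
}

#' Simulate a differential-expression results table
#'
#' Targets of each active regulator receive a log2 fold change of
#' \code{effectLog2fc} times the product of the regulator's activation sign
#' and the edge's expected regulation sign (plus Gaussian noise) and small
#' p-values; all other genes are centred on zero with null-like p-values.
#' Gene ids not covered by the network are filled in as \code{gene0001} ...
#'
#' @param network named list of data.frames(target, sign); see
#'   [readRegulatorNetwork()].
#' @param activeRegulators named integer vector: activation sign (+1/-1)
#'   per active regulator. All names must exist in the network.
#' @param nGenes universe size (>= number of distinct network targets).
#' @param effectLog2fc absolute log2 fold change given to regulated targets.
#' @param noiseSd SD of the Gaussian log2FC noise.
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{pvalue}, \code{padj} (BH).
#' @export
simulateDETable <- function(network, activeRegulators = integer(),
                            nGenes = 1000, effectLog2fc = 2, noiseSd = 0,
                            seed = NULL) {
  allTargets <- unique(unlist(lapply(network, `[[`, "target")))
  if (nGenes < length(allTargets))
    stop("nGenes must cover all network targets", call. = FALSE)
  unknown <- setdiff(names(activeRegulators), names(network))
  if (length(unknown))
    stop("unknown regulator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  filler <- sprintf("gene%04d", seq_len(nGenes - length(allTargets)))
  genes <- c(allTargets, filler)
  .withSeed(seed, {
    lfc <- stats::rnorm(nGenes, 0, noiseSd)
    pval <- stats::runif(nGenes, 0.2, 1)
    regulated <- character()
    for (reg in names(activeRegulators)) {
      tg <- network[[reg]]
      idx <- match(tg$target, genes)
      lfc[idx] <- activeRegulators[[reg]] * tg$sign * effectLog2fc +
        stats::rnorm(length(idx), 0, noiseSd)
      regulated <- union(regulated, tg$target)
    }
    if (length(regulated))
      pval[match(regulated, genes)] <-
        stats::runif(length(regulated), 1e-6, 1e-3)
    data.frame(gene = genes, log2fc = lfc, pvalue = pval,
               padj = stats::p.adjust(pval, "BH"), stringsAsFactors = FALSE)
  })
}
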