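# Whole-cohort simulation: draws per-subject ground truth from the group
# blocks of a CohortConfig, runs every modality generator, and returns an
# in-memory bundle and/or writes the per-subject file layout.

# the regulator -> target network packaged with the simulated cohorts;
# proinflammatory regulators mirror the structure (not the content) of an
# upstream-regulator analysis
.defaultNetwork <- function(nRegulators = 8L, targetsPerRegulator = 12L,
                            seed = NULL) {
  regs <- c("TNF", "IFNG", "LPS", "IL1B", "CSF2", "IL4", "REGX1", "REGX2")
  regs <- regs[seq_len(min(nRegulators, length(regs)))]
  .withSeed(seed, {
    pool <- sprintf("tgene%04d", 1:400)
    stats::setNames(lapply(seq_along(regs), function(i) {
      data.frame(
        target = sample(pool, targetsPerRegulator),
        sign = sample(c(1L, 1L, 1L, -1L), targetsPerRegulator,
                      replace = TRUE),
        stringsAsFactors = FALSE)
    }), regs)
  })
}

.drawSubjectTruth <- function(block) {
  tr <- function(nm, lower = -Inf, upper = Inf) {
    v <- block[[nm]]
    .truncDraw(1, v[1], v[2], lower, upper)
  }
  list(
    baselineIsc = tr("baselineIsc", lower = 1),
    deltaIscBumetanide = tr("deltaIscBumetanide", lower = 0),
    deltaIscAmiloride = tr("deltaIscAmiloride", lower = 0),
    rEpi = tr("rEpi", lower = 1),
    rSub = tr("rSub", lower = 0.5),
    capUF = tr("capUF", lower = 0.3),
    permFluorescein = tr("permFluorescein", lower = 0),
    permFd4 = tr("permFd4", lower = 0),
    ttjEnrichment = tr("ttjEnrichment", lower = 1),
    cryptDiameterUm = tr("cryptDiameterUm", lower = 10),
    cryptLengthUm = tr("cryptLengthUm", lower = 50),
    cryptDensityPerCm2 = tr("cryptDensityPerCm2", lower = 100),
    apoptosisFraction = tr("apoptosisFraction", lower = 0, upper = 1))
}

.simulateSubject <- function(id, group, truth, noise, seeds) {
  spectrum <- simulateImpedanceSpectrum(
    truth$rSub, truth$rEpi, truth$capUF * 1e-6,
    noiseSd = noise$impedance, seed = seeds[1], specimenId = id)
  iscBum <- simulateIscTrace(
    truth$baselineIsc,
    events = data.frame(drug = "bumetanide", time_min = 15,
                        effect = truth$deltaIscBumetanide, rate = 0.35,
                        side = "serosal"),
    duration = 45, noiseSd = noise$isc, seed = seeds[2], specimenId = id)
  iscEnac <- simulateIscTrace(
    truth$baselineIsc,
    events = data.frame(
      drug = c("aldosterone", "amiloride"), time_min = c(0, 10),
      effect = c(0, truth$deltaIscAmiloride), rate = c(0, 1),
      side = c("serosal", "mucosal")),
    duration = 30, noiseSd = noise$isc, seed = seeds[3], specimenId = id)
  fluo <- simulateFluxSeries(
    truth$permFluorescein, apicalConc = 1e-4,
    sampleTimes = c(0, 15, 30, 45, 60), noiseSd = noise$flux,
    seed = seeds[4], tracer = "fluorescein")
  fd4 <- simulateFluxSeries(
    truth$permFd4, apicalConc = 4e-4, sampleTimes = c(0, 30, 60, 90),
    noiseSd = noise$flux, seed = seeds[5], tracer = "fd4")
  profiles <- list()
  k <- 0L
  for (sec in 1:3) for (m in 1:3) {
    k <- k + 1L
    profiles[[k]] <- simulateIntensityProfile(
      enrichment = truth$ttjEnrichment, noiseSd = noise$profile,
      seed = seeds[5 + k], sectionId = paste0("sec", sec), subjectId = id)
  }
  totalDapi <- 1500L
  apoptotic <- stats::rbinom(1, totalDapi, truth$apoptosisFraction)
  list(id = id, group = group, truth = truth, impedance = spectrum,
       isc = iscBum, iscEnac = iscEnac, fluxFluorescein = fluo,
       fluxFd4 = fd4, profiles = profiles,
       morphometry = data.frame(
         inner_diameter_um = truth$cryptDiameterUm,
         crypt_length_um = truth$cryptLengthUm,
         crypts_per_cm2 = truth$cryptDensityPerCm2),
       nuclei = data.frame(apoptotic = apoptotic, total_dapi = totalDapi))
}

#' Simulate a two-group cohort
#'
#' Draws per-subject ground-truth parameters from the group blocks of a
#' [CohortConfig-class], generates every measurement modality per subject
#' (impedance spectrum, bumetanide and amiloride Isc experiments, both
#' tracer flux series with calibrations, 3 sections x 3 junctional
#' intensity profiles, crypt morphometry, nucleus counts) plus one
#' cohort-level differential-expression table with its regulator network,
#' and optionally writes the per-subject file layout to \code{dir}.
#' Fully reproducible from \code{config@seed}: the same config yields an
#' identical bundle and byte-identical files.
#'
#' @param config a [CohortConfig-class].
#' @param dir output directory (created if needed), or NULL for an
#'   in-memory bundle only.
#' @return Invisibly, a list with elements \code{subjects} (list of
#'   per-subject bundles), \code{de}, \code{network}, \code{groundTruth}
#'   and \code{config}.
#' @seealso [runPipeline()], [readCohort()]
#' @export
simulateCohort <- function(config, dir = NULL) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  bundle <- .withSeed(config@seed, {
    ids <- c(sprintf("ctrl%02d", seq_len(config@nControl)),
             sprintf("ibsm%02d", seq_len(config@nIbsm)))
    groups <- rep(c("control", "ibsm"), c(config@nControl, config@nIbsm))
    subjects <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      block <- if (groups[i] == "control") config@control else config@ibsm
      truth <- .drawSubjectTruth(block)
      seeds <- sample.int(.Machine$integer.max - 1L, 20L)
      subjects[[i]] <- .simulateSubject(ids[i], groups[i], truth,
                                        config@noise, seeds)
    }
    netSeed <- sample.int(.Machine$integer.max - 1L, 2L)
    network <- .defaultNetwork(seed = netSeed[1])
    active <- c(TNF = 1L, IFNG = 1L, LPS = 1L, IL1B = 1L)
    de <- simulateDETable(network, active, nGenes = 1000, effectLog2fc = 2,
                          noiseSd = 0.3, seed = netSeed[2])
    list(subjects = subjects, de = de, network = network,
         activeRegulators = active,
         groundTruth = list(
           seed = config@seed,
           subjects = stats::setNames(lapply(subjects, `[[`, "truth"), ids),
           groups = stats::setNames(as.list(groups), ids)),
         config = config)
  })
  if (!is.null(dir)) .writeCohort(bundle, dir)
  invisible(bundle)
}
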