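test_that("every generator is deterministic under a fixed seed", {
  a <- simulateImpedanceSpectrum(10, 50, 3e-6, noiseSd = 0.02, seed = 7)
  b <- simulateImpedanceSpectrum(10, 50, 3e-6, noiseSd = 0.02, seed = 7)
  expect_identical(a@z, b@z)
  t1 <- simulateIscTrace(100, noiseSd = 3, seed = 7)
  t2 <- simulateIscTrace(100, noiseSd = 3, seed = 7)
  expect_identical(t1@isc, t2@isc)
  f1 <- simulateFluxSeries(1e-6, noiseSd = 0.05, seed = 7)
  f2 <- simulateFluxSeries(1e-6, noiseSd = 0.05, seed = 7)
  expect_identical(f1$series@fluorescence, f2$series@fluorescence)
  expect_identical(f1$calibration, f2$calibration)
  p1 <- simulateIntensityProfile(noiseSd = 0.1, seed = 7)
  p2 <- simulateIntensityProfile(noiseSd = 0.1, seed = 7)
  expect_identical(p1@intensities, p2@intensities)
  d1 <- simulateDETable(list(R = data.frame(target = "t1", sign = 1L)),
                        nGenes = 50, noiseSd = 0.2, seed = 7)
  d2 <- simulateDETable(list(R = data.frame(target = "t1", sign = 1L)),
                        nGenes = 50, noiseSd = 0.2, seed = 7)
  expect_identical(d1, d2)
  # the ambient RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateIscTrace(1, noiseSd = 1, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("zero-noise generators emit the exact model curves", {
  sp <- simulateImpedanceSpectrum(10, 90, 3e-6, noiseSd = 0)
  expect_identical(sp@z, onePathImpedance(10, 90, 3e-6, sp@freqs))
  tr <- simulateIscTrace(100, noiseSd = 0)
  expect_true(all(tr@isc == 100))
  flat <- simulateIntensityProfile(enrichment = 1, background = 100,
                                   noiseSd = 0)
  expect_true(all(flat@intensities == 100))
  peak <- simulateIntensityProfile(enrichment = 3, background = 100,
                                   noiseSd = 0)
  expect_equal(max(peak@intensities), 300)
  expect_equal(peak@positions[which.max(peak@intensities)], peak@ttjAnchor)
})

test_that("impedance spectra respect the analytic grid-extreme limits", {
  for (p in list(c(10, 90, 3e-6), c(25, 60, 4e-6), c(8, 110, 6e-6))) {
    sp <- simulateImpedanceSpectrum(p[1], p[2], p[3], noiseSd = 0)
    expect_lt(abs(Re(sp@z)[1] - (p[1] + p[2])) / (p[1] + p[2]), 0.005)
    expect_lt(abs(Re(sp@z)[48] - p[1]) / p[1], 0.005)
  }
})

test_that("generator preconditions are enforced", {
  expect_error(simulateImpedanceSpectrum(0, 90, 3e-6), "> 0")
  expect_error(simulateImpedanceSpectrum(10, 90, 3e-6, freqs = numeric()),
               "empty")
  expect_error(simulateIscTrace(100, events = data.frame(
    drug = "x", time_min = 5, effect = 10, rate = -1)), ">= 0")
  expect_error(simulateIscTrace(100, events = data.frame(
    drug = "x", time_min = 99, effect = 10, rate = 1), duration = 45),
    "within")
  expect_error(simulateFluxSeries(-1e-6), ">= 0")
  expect_error(simulateFluxSeries(1e-6, volumeMl = 0), "> 0")
  expect_error(simulateIntensityProfile(enrichment = 0.5), ">= 1")
  expect_warning(simulateIntensityProfile(samplingUm = 2, peakWidthUm = 0.5),
                 "coarser")
})

test_that("cohort simulation is reproducible and honors zero-SD configs", {
  cfg <- defaultCohortConfig(nControl = 3, nIbsm = 3, seed = 21)
  b1 <- simulateCohort(cfg)
  b2 <- simulateCohort(cfg)
  expect_identical(b1$groundTruth, b2$groundTruth)
  expect_identical(b1$subjects[[1]]$impedance@z, b2$subjects[[1]]$impedance@z)
  expect_identical(b1$de, b2$de)

  zeroSd <- defaultCohortConfig(nControl = 3, nIbsm = 2, seed = 4)
  zeroCtl <- lapply(zeroSd@control, function(v) c(v[1], 0))
  zeroIbs <- lapply(zeroSd@ibsm, function(v) c(v[1], 0))
  cfg0 <- cohortConfig(3, 2, zeroCtl, zeroIbs, seed = 4)
  b0 <- simulateCohort(cfg0)
  for (sub in b0$subjects) {
    block <- if (sub$group == "control") zeroCtl else zeroIbs
    for (nm in names(sub$truth))
      expect_equal(sub$truth[[nm]], block[[nm]][1], tolerance = 1e-12)
  }
})

test_that("cohort directories are written byte-identically and read back", {
  cfg <- defaultCohortConfig(nControl = 2, nIbsm = 2, seed = 31)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  simulateCohort(cfg, dir = d1)
  simulateCohort(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  back <- readCohort(d1)
  expect_length(back$subjects, 4)
  expect_s4_class(back$subjects[[1]]$impedance, "ImpedanceSpectrum")
  expect_s4_class(back$subjects[[1]]$isc, "IscTrace")
  expect_equal(back$subjects[[1]]$group, "control")
  expect_true(!is.null(back$de) && !is.null(back$network))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("large-sample group means approach the configured truth", {
  cfg <- defaultCohortConfig(nControl = 200, nIbsm = 2, seed = 13)
  b <- simulateCohort(cfg)
  ctl <- Filter(function(s) s$group == "control", b$subjects)
  pull <- function(nm) vapply(ctl, function(s) s$truth[[nm]], numeric(1))
  for (nm in c("baselineIsc", "rEpi", "deltaIscBumetanide",
               "permFluorescein")) {
    v <- cfg@control[[nm]]
    se <- v[2] / sqrt(200)
    expect_lt(abs(mean(pull(nm)) - v[1]), 3 * se)
  }
})

test_that("invalid configurations are rejected by validity checks", {
  cfg <- defaultCohortConfig()
  bad <- cfg
  bad@control$rEpi <- c(-5, 2)
  expect_error(validObject(bad), "rEpi")
  bad2 <- cfg
  bad2@ibsm$apoptosisFraction <- c(1.5, 0.1)
  expect_error(validObject(bad2), "apoptosisFraction")
  bad3 <- cfg
  bad3@control$baselineIsc <- c(100, -1)
  expect_error(validObject(bad3), "SD")
  expect_error(cohortConfig(0, 3, cfg@control, cfg@ibsm), ">= 1")
})
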