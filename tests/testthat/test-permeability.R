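test_that("calibration fitting averages duplicates before OLS", {
  conc <- rep(c(1e-8, 5e-8, 1e-7), each = 2)
  perfect <- fitCalibration(conc, 2e9 * conc)
  expect_equal(perfect@gain, 2e9, tolerance = 1e-9)
  expect_equal(perfect@intercept, 0, tolerance = 1e-3)
  expect_equal(perfect@r2, 1)
  # duplicates offset by -1/+1 around a gain-2 line average away exactly
  jitter <- fitCalibration(conc, 2e9 * conc + c(-1, 1))
  expect_equal(jitter@gain, 2e9, tolerance = 1e-9)
  expect_error(fitCalibration(rep(1e-7, 6), rnorm(6)), "at least 3")
  expect_error(fitCalibration(conc, rep(5, 6)), "not positive")
  expect_error(fitCalibration(rep(c(1e-8, 1e-7), each = 2), rep(1:2, 2)),
               "at least 3")
})

test_that("the worked flux example gives J = 40.8 nmol/h/cm2, P = 1.134e-4 cm/s", {
  fs <- FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                   amounts = c(0, 0.5, 1, 1.5, 2), amountUnit = "nmol",
                   apicalConc = 1e-4, area = 0.049)
  res <- fluxFromSeries(fs)
  expect_equal(flux(res), 2e-9 / 0.049, tolerance = 1e-12)      # 40.8 nmol/h/cm2
  expect_equal(permeability(res), 1.134e-4, tolerance = 5e-4)   # printed precision
  # the P = J/dc identity holds exactly in the stored record
  expect_equal(permeability(res), flux(res) / 3600 / (1e-4 * 1e-3),
               tolerance = 1e-15)
  expect_equal(res@r2, 1)
})

test_that("zero-noise simulation round-trips permeability exactly", {
  for (p in 10^seq(-8, -4)) {
    sim <- simulateFluxSeries(p, noiseSd = 0)
    calib <- fitCalibration(sim$calibration$conc_mol_l,
                            sim$calibration$fluorescence)
    rec <- fluxFromSeries(sim$series, calib)
    expect_equal(permeability(rec), p, tolerance = 1e-9)
  }
  # zero permeability: no accumulation at all
  sim0 <- simulateFluxSeries(0, noiseSd = 0)
  calib0 <- fitCalibration(sim0$calibration$conc_mol_l,
                           sim0$calibration$fluorescence)
  rec0 <- fluxFromSeries(sim0$series, calib0)
  expect_equal(flux(rec0), 0, tolerance = 1e-20)
  expect_equal(permeability(rec0), 0, tolerance = 1e-15)
})

test_that("P scales with the appearance slope and inversely with dc", {
  base <- fluxFromSeries(FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                                    amounts = c(0, 1, 2, 3, 4) * 1e-9,
                                    apicalConc = 1e-4))
  doubled <- fluxFromSeries(FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                                       amounts = c(0, 2, 4, 6, 8) * 1e-9,
                                       apicalConc = 1e-4))
  halfDc <- fluxFromSeries(FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                                      amounts = c(0, 1, 2, 3, 4) * 1e-9,
                                      apicalConc = 5e-5))
  expect_equal(permeability(doubled), 2 * permeability(base),
               tolerance = 1e-12)
  expect_equal(permeability(halfDc), 2 * permeability(base),
               tolerance = 1e-12)
})

test_that("declared amount units do not change the result", {
  inNmol <- FluxSeries("fd4", c(0, 30, 60, 90), amounts = c(0, 1, 2, 3),
                       amountUnit = "nmol", apicalConc = 4e-4)
  inMol <- FluxSeries("fd4", c(0, 30, 60, 90), amounts = c(0, 1, 2, 3) * 1e-9,
                      amountUnit = "mol", apicalConc = 4e-4)
  expect_equal(permeability(fluxFromSeries(inNmol)),
               permeability(fluxFromSeries(inMol)), tolerance = 1e-12)
})

test_that("degenerate series are refused or flagged", {
  short <- FluxSeries("fluorescein", c(0, 30), amounts = c(0, 1e-9),
                      apicalConc = 1e-4)
  expect_error(fluxFromSeries(short), "at least 3")
  noCal <- FluxSeries("fluorescein", c(0, 15, 30, 45),
                      fluorescence = c(10, 20, 30, 40), apicalConc = 1e-4)
  expect_error(fluxFromSeries(noCal), "CalibrationCurve")
  declining <- FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                          amounts = c(4, 3, 2, 1, 0) * 1e-9,
                          apicalConc = 1e-4)
  expect_true("negative-slope" %in% fluxFromSeries(declining)@flags)
  # skipFirst drops the t = 0 point
  lagged <- FluxSeries("fluorescein", c(0, 15, 30, 45, 60),
                       amounts = c(0.5, 1, 2, 3, 4) * 1e-9,
                       apicalConc = 1e-4)
  full <- fluxFromSeries(lagged)
  skipped <- fluxFromSeries(lagged, skipFirst = TRUE)
  expect_equal(skipped@nPoints, 4)
  expect_gt(flux(skipped), flux(full))
})
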