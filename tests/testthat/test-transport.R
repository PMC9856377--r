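makeStepTrace <- function(baseline, drug, t0, effect, rate,
                          duration = 45, dt = 0.5) {
  simulateIscTrace(baseline,
                   events = data.frame(drug = drug, time_min = t0,
                                       effect = effect, rate = rate),
                   duration = duration, dt = dt, noiseSd = 0)
}

test_that("baseline Isc is the mean of the pre-event window", {
  expect_equal(baselineIsc(IscTrace(0:10, rep(100, 11))), 100)
  tr <- IscTrace(c(0, 5, 10, 20), c(130, 146, 60, 60),
                 drugEvents("bumetanide", 8, "serosal"))
  expect_equal(baselineIsc(tr), 138)
  short <- IscTrace(c(0, 5, 10), c(100, 60, 60),
                    drugEvents("bumetanide", 2, "serosal"))
  expect_error(baselineIsc(short), "at least 2 samples")
})

test_that("bumetanide response is max-before minus the +20 min reading", {
  tr <- makeStepTrace(100, "bumetanide", 10, 40, rate = 3)
  resp <- bumetanideResponse(tr)
  expect_equal(deltaIsc(resp), 40, tolerance = 1e-6)
  expect_equal(resp@preValue, 100)
  # flat trace gives a zero response
  flat <- makeStepTrace(100, "bumetanide", 10, 0, rate = 3)
  expect_equal(deltaIsc(bumetanideResponse(flat)), 0, tolerance = 1e-12)
  # a trace ending before +20 min is refused, naming the horizon
  shortTr <- makeStepTrace(100, "bumetanide", 10, 40, 3, duration = 25)
  expect_error(bumetanideResponse(shortTr), "20 min")
  expect_error(bumetanideResponse(IscTrace(0:40, rep(1, 41))),
               "no 'bumetanide' event")
})

test_that("amiloride response is the plateau difference, signed and flagged", {
  t <- seq(0, 30, by = 1)
  isc <- ifelse(t < 10, 80, 50)
  tr <- IscTrace(t, isc, drugEvents("amiloride", 10, "mucosal"))
  resp <- amilorideJNa(tr)
  expect_equal(deltaIsc(resp), 30)
  expect_length(resp@flags, 0)
  # no ENaC activity: pre == post
  flat <- IscTrace(t, rep(80, length(t)), drugEvents("amiloride", 10, "mucosal"))
  expect_equal(deltaIsc(amilorideJNa(flat)), 0)
  # a current increase is returned negative and flagged, not truncated
  up <- IscTrace(t, ifelse(t < 10, 50, 80),
                 drugEvents("amiloride", 10, "mucosal"))
  respUp <- amilorideJNa(up)
  expect_equal(deltaIsc(respUp), -30)
  expect_true("negative-response" %in% respUp@flags)
})

test_that("drug responses are invariant to a constant shift of the trace", {
  trB <- makeStepTrace(100, "bumetanide", 10, 40, 3)
  trA <- simulateIscTrace(80, events = data.frame(
    drug = "amiloride", time_min = 10, effect = 30, rate = 2),
    duration = 30, noiseSd = 0)
  for (shift in c(-25, 50)) {
    shiftedB <- IscTrace(trB@time, trB@isc + shift, trB@events)
    shiftedA <- IscTrace(trA@time, trA@isc + shift, trA@events)
    expect_equal(deltaIsc(bumetanideResponse(shiftedB)),
                 deltaIsc(bumetanideResponse(trB)), tolerance = 1e-12)
    expect_equal(deltaIsc(amilorideJNa(shiftedA)),
                 deltaIsc(amilorideJNa(trA)), tolerance = 1e-12)
  }
})

test_that("recovered delta-Isc scales linearly with the simulated effect", {
  d1 <- deltaIsc(bumetanideResponse(makeStepTrace(100, "bumetanide", 10, 20, 3)))
  d2 <- deltaIsc(bumetanideResponse(makeStepTrace(100, "bumetanide", 10, 40, 3)))
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("current-to-flux conversion follows Faraday arithmetic", {
  expect_equal(iscToMolarFlux(0, 1), 0)
  expect_equal(iscToMolarFlux(1, 1), 0.0373, tolerance = 1e-3)
  expect_equal(iscToMolarFlux(96.485, 1), 3.6, tolerance = 1e-12)
  # linear and sign-preserving
  expect_equal(iscToMolarFlux(-10, 1), -10 * iscToMolarFlux(1, 1))
  expect_equal(iscToMolarFlux(5, 2), iscToMolarFlux(5, 1) / 2)
  expect_error(iscToMolarFlux(10, 0), "non-zero")
})

test_that("equal-J_Na groups stay non-significant at the nominal rate", {
  # control vs IBS-M with identical amiloride effects: expect ~5% rejections
  reject <- vapply(1:30, function(s) {
    vals <- function(offset) vapply(1:8, function(i) {
      tr <- simulateIscTrace(80, events = data.frame(
        drug = "amiloride", time_min = 10, effect = 15, rate = 1),
        duration = 30, noiseSd = 2, seed = s * 100 + offset + i)
      deltaIsc(amilorideJNa(tr))
    }, numeric(1))
    twoGroupTTest(vals(0), vals(50))$p < 0.05
  }, logical(1))
  expect_lt(mean(reject), 0.2)
})
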