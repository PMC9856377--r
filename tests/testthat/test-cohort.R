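test_that("t statistics and p-values match the reference implementation", {
  set.seed(29)
  for (i in 1:50) {
    a <- rnorm(sample(3:15, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    b <- rnorm(sample(3:15, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    pooled <- twoGroupTTest(a, b, "pooled")
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pooled$p, ref$p.value, tolerance = 1e-10)
    welch <- twoGroupTTest(a, b, "welch")
    refW <- t.test(a, b)
    expect_equal(welch$t, unname(refW$statistic), tolerance = 1e-12)
    expect_equal(welch$p, refW$p.value, tolerance = 1e-10)
  }
})

test_that("summary-statistic path reproduces the raw-data path", {
  set.seed(30)
  for (i in 1:20) {
    a <- rnorm(8, 10, 3)
    b <- rnorm(6, 8, 2)
    raw <- twoGroupTTest(a, b, "pooled")
    summ <- tTestFromSummary(mean(a), sd(a), 8, mean(b), sd(b), 6, "pooled")
    expect_equal(summ$t, raw$t, tolerance = 1e-12)
    expect_equal(summ$p, raw$p, tolerance = 1e-12)
  }
  # the published baseline-Isc summaries: pooled recomputation
  pub <- tTestFromSummary(138, 75, 10, 74, 35, 6)
  expect_equal(pub$t, 1.95, tolerance = 1e-2)
  expect_equal(pub$p, 0.072, tolerance = 1e-2)
  expect_equal(pub$label, "n.s.")
  # degenerate zero-variance limit
  degen <- tTestFromSummary(10, 0, 5, 8, 0, 5)
  expect_equal(degen$p, 0)
  expect_equal(degen$label, "***")
  expect_equal(tTestFromSummary(5, 1, 5, 5, 1, 5)$t, 0)
  expect_error(tTestFromSummary(1, 1, 1, 2, 1, 5), ">= 2")
  expect_error(twoGroupTTest(c(1, 2), c(3, NA)), "finite")
})

test_that("significance labels are consistent with their p-values", {
  expect_equal(significanceLabel(c(1, 0.05, 0.049, 0.01, 0.009, 0.001, 1e-5)),
               c("n.s.", "n.s.", "*", "*", "**", "**", "***"))
  set.seed(31)
  for (i in 1:100) {
    cmp <- twoGroupTTest(rnorm(5), rnorm(5))
    lab <- cmp$label
    p <- cmp$p
    expect_equal(lab, significanceLabel(p))
    if (p >= 0.05) expect_equal(lab, "n.s.")
    if (p < 0.001) expect_equal(lab, "***")
  }
})

test_that("the pipeline produces per-subject metrics and group tables", {
  cfg <- defaultCohortConfig(nControl = 3, nIbsm = 3, seed = 5)
  dir <- file.path(tempdir(), "cohort_pipe")
  out <- file.path(tempdir(), "report_pipe")
  unlink(c(dir, out), recursive = TRUE)
  simulateCohort(cfg, dir = dir)
  rep <- runPipeline(dir, outDir = out)
  expect_equal(nrow(rep$metrics), 6)
  expect_true(all(c("r_epi", "baseline_isc", "delta_isc_bumetanide",
                    "j_na", "p_fluorescein", "p_fd4", "ttj_ratio",
                    "surface_ratio", "apoptosis_rate") %in%
                  names(rep$metrics)))
  expect_true(all(is.finite(rep$metrics$r_epi)))
  expect_true(all(rep$comparisons$label ==
                  significanceLabel(rep$comparisons$p)))
  expect_true(file.exists(file.path(out, "metrics_per_subject.tsv")))
  expect_true(file.exists(file.path(out, "group_comparisons.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "run.log")))
  # j_na is the Faraday conversion of the amiloride response
  expect_equal(rep$metrics$j_na,
               iscToMolarFlux(rep$metrics$delta_isc_amiloride, 1),
               tolerance = 1e-12)
  # regulator ranking ran on the cohort-level DE table
  expect_false(is.null(rep$regulators))
  expect_true(all(c("TNF", "IFNG") %in% rep$regulators$regulator))
  unlink(c(dir, out), recursive = TRUE)
})

test_that("missing modality files are skipped per metric, not fatally", {
  cfg <- defaultCohortConfig(nControl = 3, nIbsm = 3, seed = 6)
  dir <- file.path(tempdir(), "cohort_missing")
  unlink(dir, recursive = TRUE)
  simulateCohort(cfg, dir = dir)
  unlink(file.path(dir, "ctrl01", "impedance.csv"))
  unlink(file.path(dir, "ibsm01", "flux_fluorescein.csv"))
  rep <- runPipeline(dir)
  m <- rep$metrics
  expect_true(is.na(m$r_epi[m$subject == "ctrl01"]))
  expect_true(is.na(m$p_fluorescein[m$subject == "ibsm01"]))
  expect_true(all(is.finite(m$baseline_isc)))
  expect_true(any(grepl("no spectrum", rep$log)))
  # group comparisons still computed from the remaining subjects
  expect_true("r_epi" %in% rep$comparisons$metric)
  unlink(dir, recursive = TRUE)
})

test_that("an empty cohort yields an all-skipped report, not an error", {
  dir <- file.path(tempdir(), "cohort_empty")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  write.csv(data.frame(subject = character(), group = character()),
            file.path(dir, "subjects.csv"), row.names = FALSE)
  rep <- runPipeline(dir)
  expect_equal(nrow(rep$metrics), 0)
  expect_equal(nrow(rep$comparisons), 0)
  expect_true(any(grepl("empty cohort", rep$log)))
  unlink(dir, recursive = TRUE)
})
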