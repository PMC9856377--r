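# Group-level statistics and end-to-end orchestration.

#' Significance label for a p-value
#'
#' Three-star convention: n.s. for p >= 0.05, * for p < 0.05, ** for
#' p < 0.01, *** for p < 0.001.
#'
#' @param p p-value(s).
#' @return Character vector of labels.
#' @export
significanceLabel <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "n.s.")))
}

.ttestCore <- function(meanA, sdA, nA, meanB, sdB, nB, variant) {
  if (variant == "pooled") {
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    vA <- sdA^2 / nA
    vB <- sdB^2 / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  }
  t <- (meanA - meanB) / se
  p <- if (se == 0) {
    if (meanA == meanB) 1 else 0  # degenerate zero-variance limit
  } else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

.comparisonRow <- function(metric, meanA, sdA, nA, meanB, sdB, nB, variant) {
  ct <- .ttestCore(meanA, sdA, nA, meanB, sdB, nB, variant)
  data.frame(metric = metric, mean_control = meanA, sd_control = sdA,
             n_control = nA, mean_ibsm = meanB, sd_ibsm = sdB, n_ibsm = nB,
             t = ct$t, df = ct$df, p = ct$p,
             label = significanceLabel(ct$p), variant = variant,
             stringsAsFactors = FALSE)
}

#' Two-group comparison by Student's t-test
#'
#' Two-sided t-test on raw per-subject values, pooled-variance Student by
#' default (Welch by \code{variant = "welch"}). Groups are summarized as
#' mean and SD. The returned one-row data.frame carries the group
#' summaries, the t statistic, degrees of freedom, p-value and the
#' three-star significance label.
#'
#' @param valuesA,valuesB numeric vectors, each of length >= 2, finite.
#' @param variant "pooled" or "welch".
#' @param metric metric name for the output row.
#' @return One-row data.frame (see [significanceLabel()] for labels).
#' @examples
#' twoGroupTTest(rnorm(10, 138, 75), rnorm(6, 74, 35))
#' @export
twoGroupTTest <- function(valuesA, valuesB, variant = c("pooled", "welch"),
                          metric = "metric") {
  variant <- match.arg(variant)
  for (v in list(valuesA, valuesB))
    if (length(v) < 2L || any(!is.finite(v)))
      stop("each group needs >= 2 finite values", call. = FALSE)
  .comparisonRow(metric, mean(valuesA), stats::sd(valuesA), length(valuesA),
                 mean(valuesB), stats::sd(valuesB), length(valuesB), variant)
}

#' Two-group t-test from published summary statistics
#'
#' Computes the same test as [twoGroupTTest()] directly from group means,
#' SDs and sizes, so printed mean +/- SD tables can be checked. For the
#' pooled variant this is algebraically identical to the raw-data path on
#' any data with those summaries.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (sd >= 0, n >= 2).
#' @param variant "pooled" or "welch".
#' @param metric metric name for the output row.
#' @return One-row data.frame as in [twoGroupTTest()].
#' @examples
#' tTestFromSummary(138, 75, 10, 74, 35, 6)  # t = 1.95, p = 0.072
#' @export
tTestFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                             variant = c("pooled", "welch"),
                             metric = "metric") {
  variant <- match.arg(variant)
  .assertScalar(sdA, "sdA", nonNegative = TRUE)
  .assertScalar(sdB, "sdB", nonNegative = TRUE)
  if (nA < 2 || nB < 2) stop("group sizes must be >= 2", call. = FALSE)
  .comparisonRow(metric, meanA, sdA, nA, meanB, sdB, nB, variant)
}

# ---- pipeline ----

.tryMetric <- function(log, metric, expr) {
  tryCatch(expr, error = function(e) {
    log(paste0("skipping ", metric, ": ", conditionMessage(e)))
    NA_real_
  })
}

.subjectMetrics <- function(sub, log) {
  id <- sub$id
  logm <- function(msg) log(paste0("[", id, "] ", msg))
  fit <- if (is.null(sub$impedance)) {
    logm("skipping impedance metrics: no spectrum")
    NULL
  } else .tryMetric(logm, "impedance fit", fitOnePath(sub$impedance))
  fluxP <- function(fx, name) {
    if (is.null(fx)) {
      logm(paste0("skipping ", name, ": no flux series"))
      return(NA_real_)
    }
    .tryMetric(logm, name, {
      calib <- fitCalibration(fx$calibration$conc_mol_l,
                              fx$calibration$fluorescence)
      permeability(fluxFromSeries(fx$series, calib))
    })
  }
  ttj <- if (is.null(sub$profiles)) {
    logm("skipping ttj_ratio: no profiles")
    NA_real_
  } else .tryMetric(logm, "ttj_ratio", {
    ratios <- vapply(sub$profiles, function(p) as.numeric(ttjBtjRatio(p)),
                     numeric(1))
    sections <- vapply(sub$profiles, function(p) p@sectionId, "")
    subjectMean(aggregateSubject(ratios, sections, subjectId = id))
  })
  data.frame(
    subject = id, group = sub$group,
    r_epi = if (is.null(fit) || !is(fit, "OnePathFit")) NA_real_ else rEpi(fit),
    r_sub = if (is.null(fit) || !is(fit, "OnePathFit")) NA_real_ else rSub(fit),
    cap_uf = if (is.null(fit) || !is(fit, "OnePathFit")) NA_real_ else
      capacitance(fit) * 1e6,
    baseline_isc = if (is.null(sub$isc)) {
      logm("skipping baseline_isc: no trace"); NA_real_
    } else .tryMetric(logm, "baseline_isc", baselineIsc(sub$isc)),
    delta_isc_bumetanide = if (is.null(sub$isc)) NA_real_ else
      .tryMetric(logm, "delta_isc_bumetanide",
                 deltaIsc(bumetanideResponse(sub$isc))),
    delta_isc_amiloride = if (is.null(sub$iscEnac)) {
      logm("skipping amiloride metrics: no trace"); NA_real_
    } else .tryMetric(logm, "delta_isc_amiloride",
                      deltaIsc(amilorideJNa(sub$iscEnac))),
    p_fluorescein = fluxP(sub$fluxFluorescein, "p_fluorescein"),
    p_fd4 = fluxP(sub$fluxFd4, "p_fd4"),
    ttj_ratio = ttj,
    surface_ratio = if (is.null(sub$morphometry)) {
      logm("skipping surface_ratio: no morphometry"); NA_real_
    } else .tryMetric(logm, "surface_ratio", surfaceRatio(
      sub$morphometry$inner_diameter_um[1],
      sub$morphometry$crypt_length_um[1],
      sub$morphometry$crypts_per_cm2[1])),
    apoptosis_rate = if (is.null(sub$nuclei)) {
      logm("skipping apoptosis_rate: no nuclei counts"); NA_real_
    } else .tryMetric(logm, "apoptosis_rate", apoptosisRate(
      sub$nuclei$apoptotic[1], sub$nuclei$total_dapi[1])),
    stringsAsFactors = FALSE)
}

#' Run the full per-subject and group-level analysis
#'
#' Computes every per-subject metric (epithelial and subepithelial
#' resistance, capacitance, baseline Isc, bumetanide-sensitive delta-Isc,
#' amiloride-sensitive delta-Isc with its molar-flux conversion J_Na,
#' tracer permeabilities, subject-mean tTJ/bTJ ratio, mucosal surface
#' ratio, apoptosis rate), then compares the groups metric-by-metric with
#' the pooled Student's t-test, and (when a DE table and network are
#' present) ranks upstream regulators. Missing modalities are skipped per
#' metric with a logged warning, not a global failure.
#'
#' @param cohort a cohort directory path, or an in-memory bundle from
#'   [simulateCohort()].
#' @param outDir if non-NULL, writes \code{metrics_per_subject.tsv},
#'   \code{group_comparisons.tsv}, \code{regulators.tsv},
#'   \code{summary.json} and \code{run.log} there.
#' @param variant t-test variant, "pooled" (default) or "welch".
#' @return List with \code{metrics} (per-subject data.frame),
#'   \code{comparisons} (one row per metric), \code{regulators}
#'   (data.frame or NULL) and \code{log} (character).
#' @export
runPipeline <- function(cohort, outDir = NULL,
                        variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  bundle <- if (is.character(cohort)) readCohort(cohort) else cohort
  logLines <- character()
  log <- function(msg) logLines <<- c(logLines, msg)
  metrics <- do.call(rbind, lapply(bundle$subjects, .subjectMetrics,
                                   log = log))
  if (!is.null(metrics) && nrow(metrics)) {
    metrics$j_na <- iscToMolarFlux(metrics$delta_isc_amiloride, charge = 1)
  } else {
    metrics <- data.frame()
    log("empty cohort: no subjects found")
  }
  metricCols <- setdiff(names(metrics), c("subject", "group"))
  comparisons <- list()
  for (m in metricCols) {
    a <- metrics[[m]][metrics$group == "control"]
    b <- metrics[[m]][metrics$group == "ibsm"]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) >= 2 && length(b) >= 2) {
      comparisons[[m]] <- twoGroupTTest(a, b, variant = variant, metric = m)
    } else {
      log(paste0("skipping group comparison for ", m,
                 ": fewer than 2 values per group"))
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
                 else data.frame()
  rownames(comparisons) <- NULL
  regulators <- NULL
  if (!is.null(bundle$de) && !is.null(bundle$network)) {
    regulators <- tryCatch(
      rankRegulators(bundle$de, bundle$network),
      error = function(e) {
        log(paste0("skipping regulator ranking: ", conditionMessage(e)))
        NULL
      })
  } else log("skipping regulator ranking: no DE table or network")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics, file.path(outDir, "metrics_per_subject.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(comparisons,
                       file.path(outDir, "group_comparisons.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(regulators))
      utils::write.table(regulators, file.path(outDir, "regulators.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    summary <- list(
      n_subjects = nrow(metrics),
      metrics = metricCols,
      comparisons = if (nrow(comparisons)) comparisons else NULL,
      top_regulator = if (!is.null(regulators) && nrow(regulators))
        regulators$regulator[1] else NULL)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  list(metrics = metrics, comparisons = comparisons,
       regulators = regulators, log = logLines)
}
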