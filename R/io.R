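# Plain-text readers and writers for the per-subject cohort layout.

#' Read an impedance spectrum from CSV
#'
#' Expects columns \code{freq_hz}, \code{z_real}, \code{z_imag}.
#'
#' @param path CSV file path.
#' @param bathCorrected whether the stored values are already
#'   bath-corrected.
#' @param specimenId identifier (defaults to the file name).
#' @return An [ImpedanceSpectrum-class].
#' @export
readImpedanceCsv <- function(path, bathCorrected = TRUE,
                             specimenId = basename(path)) {
  d <- utils::read.csv(path)
  ImpedanceSpectrum(d$freq_hz, complex(real = d$z_real, imaginary = d$z_imag),
                    bathCorrected = bathCorrected, specimenId = specimenId)
}

#' Read an Isc trace and its drug events from CSV
#'
#' @param iscPath CSV with columns \code{time_min}, \code{isc_ua_cm2}.
#' @param eventsPath CSV with columns \code{drug}, \code{time_min},
#'   \code{side}; NULL for an event-free trace.
#' @param specimenId identifier.
#' @return An [IscTrace-class].
#' @export
readIscCsv <- function(iscPath, eventsPath = NULL,
                       specimenId = basename(iscPath)) {
  d <- utils::read.csv(iscPath)
  ev <- if (is.null(eventsPath)) drugEvents() else {
    e <- utils::read.csv(eventsPath)
    drugEvents(e$drug, e$time_min, e$side)
  }
  IscTrace(d$time_min, d$isc_ua_cm2, ev, specimenId = specimenId)
}

#' Read a tracer flux series from CSV
#'
#' The measurement column is declared by its header: \code{fluorescence}
#' (raw plate-reader units, converted downstream through a calibration
#' curve), \code{amount_mol} or \code{amount_nmol}. Chamber geometry and
#' the apical concentration are carried in constant columns
#' \code{apical_conc_mol_l}, \code{area_cm2}, \code{volume_ml}.
#'
#' @param path CSV file path.
#' @param tracer tracer name; defaults to the file name pattern
#'   \code{flux_<tracer>.csv}.
#' @return A [FluxSeries-class].
#' @export
readFluxSeriesCsv <- function(path,
                              tracer = sub("^flux_(.*)\\.csv$", "\\1",
                                           basename(path))) {
  d <- utils::read.csv(path)
  args <- list(tracer = tracer, times = d$time_min,
               apicalConc = d$apical_conc_mol_l[1], area = d$area_cm2[1],
               volumeMl = d$volume_ml[1])
  if ("fluorescence" %in% names(d)) {
    args$fluorescence <- d$fluorescence
  } else if ("amount_mol" %in% names(d)) {
    args$amounts <- d$amount_mol; args$amountUnit <- "mol"
  } else if ("amount_nmol" %in% names(d)) {
    args$amounts <- d$amount_nmol; args$amountUnit <- "nmol"
  } else {
    stop("no fluorescence, amount_mol or amount_nmol column in ", path,
         call. = FALSE)
  }
  do.call(FluxSeries, args)
}

#' Read a calibration dilution series from CSV
#'
#' Expects columns \code{conc_mol_l} and \code{fluorescence} (duplicate
#' rows per dilution point).
#'
#' @param path CSV file path.
#' @return A [CalibrationCurve-class] (already fitted).
#' @export
readCalibrationCsv <- function(path) {
  d <- utils::read.csv(path)
  fitCalibration(d$conc_mol_l, d$fluorescence)
}

#' Read junctional intensity profiles from CSV
#'
#' @param profilesPath CSV with columns \code{profile_id}, \code{pos_um},
#'   \code{intensity}.
#' @param metaPath CSV with columns \code{profile_id}, \code{subject},
#'   \code{section}, \code{anchor_um} (and optionally \code{group}).
#' @return Named list of [IntensityProfile-class] objects, one per
#'   profile id.
#' @export
readIntensityProfilesCsv <- function(profilesPath, metaPath) {
  prof <- utils::read.csv(profilesPath)
  meta <- utils::read.csv(metaPath)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    rows <- prof[prof$profile_id == meta$profile_id[i], ]
    IntensityProfile(rows$pos_um, rows$intensity,
                     ttjAnchor = meta$anchor_um[i],
                     sectionId = as.character(meta$section[i]),
                     subjectId = as.character(meta$subject[i]))
  })
  stats::setNames(out, meta$profile_id)
}

#' Read a DESeq2-style differential-expression results table
#'
#' Tab-separated with columns \code{gene}, \code{log2fc}, \code{pvalue},
#' \code{padj}.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readDEResults <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "padj")
  if (!all(need %in% names(d)))
    stop("DE results need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' Read or write a signed regulator network (GMT-like TSV)
#'
#' One line per regulator-sign stratum:
#' \code{regulator <tab> sign <tab> target1 <tab> target2 ...}; a regulator
#' with both activating and repressing edges spans two lines.
#'
#' @param path TSV file path.
#' @return \code{readRegulatorNetwork}: a named list,
#'   \code{network[[regulator]]} = data.frame(target, sign).
#' @export
readRegulatorNetwork <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  net <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed network line: ", substr(ln, 1, 60), call. = FALSE)
    reg <- f[1]
    sgn <- as.integer(f[2])
    if (!sgn %in% c(-1L, 1L))
      stop("regulation sign must be +1 or -1 (regulator ", reg, ")",
           call. = FALSE)
    add <- data.frame(target = f[-(1:2)], sign = sgn,
                      stringsAsFactors = FALSE)
    net[[reg]] <- if (is.null(net[[reg]])) add else rbind(net[[reg]], add)
  }
  for (reg in names(net))
    if (anyDuplicated(net[[reg]]$target))
      stop("duplicate target for regulator '", reg, "'", call. = FALSE)
  net
}

#' @rdname readRegulatorNetwork
#' @param network named list of data.frames(target, sign).
#' @export
writeRegulatorNetwork <- function(network, path) {
  lines <- character()
  for (reg in names(network)) {
    tg <- network[[reg]]
    for (s in unique(tg$sign)) {
      lines <- c(lines, paste(c(reg, s, tg$target[tg$sign == s]),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- cohort directory layout ----

.writeCsv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

.fluxCsv <- function(fx) {
  s <- fx$series
  data.frame(time_min = s@times, fluorescence = s@fluorescence,
             apical_conc_mol_l = s@apicalConc, area_cm2 = s@area,
             volume_ml = s@volumeMl)
}

.writeCohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  for (sub in bundle$subjects) {
    sdir <- file.path(dir, sub$id)
    dir.create(sdir, showWarnings = FALSE)
    sp <- sub$impedance
    .writeCsv(data.frame(freq_hz = sp@freqs, z_real = Re(sp@z),
                         z_imag = Im(sp@z)),
              file.path(sdir, "impedance.csv"))
    .writeCsv(data.frame(time_min = sub$isc@time,
                         isc_ua_cm2 = sub$isc@isc),
              file.path(sdir, "isc.csv"))
    .writeCsv(sub$isc@events, file.path(sdir, "events.csv"))
    .writeCsv(data.frame(time_min = sub$iscEnac@time,
                         isc_ua_cm2 = sub$iscEnac@isc),
              file.path(sdir, "isc_enac.csv"))
    .writeCsv(sub$iscEnac@events, file.path(sdir, "events_enac.csv"))
    .writeCsv(.fluxCsv(sub$fluxFluorescein),
              file.path(sdir, "flux_fluorescein.csv"))
    .writeCsv(sub$fluxFluorescein$calibration,
              file.path(sdir, "calibration_fluorescein.csv"))
    .writeCsv(.fluxCsv(sub$fluxFd4), file.path(sdir, "flux_fd4.csv"))
    .writeCsv(sub$fluxFd4$calibration,
              file.path(sdir, "calibration_fd4.csv"))
    profRows <- do.call(rbind, lapply(seq_along(sub$profiles), function(k) {
      p <- sub$profiles[[k]]
      data.frame(profile_id = sprintf("%s_p%02d", sub$id, k),
                 pos_um = p@positions, intensity = p@intensities)
    }))
    metaRows <- do.call(rbind, lapply(seq_along(sub$profiles), function(k) {
      p <- sub$profiles[[k]]
      data.frame(profile_id = sprintf("%s_p%02d", sub$id, k),
                 subject = sub$id, section = p@sectionId,
                 anchor_um = p@ttjAnchor, group = sub$group)
    }))
    .writeCsv(profRows, file.path(sdir, "profiles.csv"))
    .writeCsv(metaRows, file.path(sdir, "profile_meta.csv"))
    .writeCsv(sub$morphometry, file.path(sdir, "morphometry.csv"))
    .writeCsv(sub$nuclei, file.path(sdir, "nuclei.csv"))
  }
  .writeCsv(data.frame(
    subject = vapply(bundle$subjects, `[[`, "", "id"),
    group = vapply(bundle$subjects, `[[`, "", "group")),
    file.path(dir, "subjects.csv"))
  utils::write.table(bundle$de, file.path(dir, "de_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeRegulatorNetwork(bundle$network, file.path(dir, "network.tsv"))
  jsonlite::write_json(bundle$groundTruth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- bundle$config
  jsonlite::write_json(
    list(nControl = cfg@nControl, nIbsm = cfg@nIbsm, control = cfg@control,
         ibsm = cfg@ibsm, noise = cfg@noise, seed = cfg@seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load a cohort directory into an analysis bundle
#'
#' Reads the layout written by [simulateCohort()] (or any directory matching
#' it). Missing modality files are tolerated and show up as NULL entries;
#' [runPipeline()] skips the corresponding metrics with a logged warning.
#'
#' @param dir cohort directory containing \code{subjects.csv} and one
#'   sub-directory per subject.
#' @return A bundle list as produced by [simulateCohort()] (without ground
#'   truth unless \code{ground_truth.json} is present).
#' @export
readCohort <- function(dir) {
  manifest <- file.path(dir, "subjects.csv")
  if (!file.exists(manifest))
    stop("no subjects.csv manifest in ", dir, call. = FALSE)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  tryFile <- function(path, reader, ...)
    if (file.exists(path)) reader(path, ...) else NULL
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$subject[i]
    sdir <- file.path(dir, id)
    fluxOf <- function(tracer) {
      fp <- file.path(sdir, paste0("flux_", tracer, ".csv"))
      cp <- file.path(sdir, paste0("calibration_", tracer, ".csv"))
      if (!file.exists(fp)) return(NULL)
      list(series = readFluxSeriesCsv(fp, tracer = tracer),
           calibration = if (file.exists(cp)) utils::read.csv(cp) else NULL)
    }
    profiles <- if (file.exists(file.path(sdir, "profiles.csv")) &&
                    file.exists(file.path(sdir, "profile_meta.csv")))
      readIntensityProfilesCsv(file.path(sdir, "profiles.csv"),
                               file.path(sdir, "profile_meta.csv"))
    else NULL
    isc <- if (file.exists(file.path(sdir, "isc.csv")))
      readIscCsv(file.path(sdir, "isc.csv"),
                 eventsPath = if (file.exists(file.path(sdir, "events.csv")))
                   file.path(sdir, "events.csv") else NULL,
                 specimenId = id)
    else NULL
    iscEnac <- if (file.exists(file.path(sdir, "isc_enac.csv")))
      readIscCsv(file.path(sdir, "isc_enac.csv"),
                 eventsPath =
                   if (file.exists(file.path(sdir, "events_enac.csv")))
                     file.path(sdir, "events_enac.csv") else NULL,
                 specimenId = id)
    else NULL
    list(id = id, group = man$group[i],
         impedance = tryFile(file.path(sdir, "impedance.csv"),
                             readImpedanceCsv, specimenId = id),
         isc = isc, iscEnac = iscEnac,
         fluxFluorescein = fluxOf("fluorescein"), fluxFd4 = fluxOf("fd4"),
         profiles = profiles,
         morphometry = tryFile(file.path(sdir, "morphometry.csv"),
                               utils::read.csv),
         nuclei = tryFile(file.path(sdir, "nuclei.csv"), utils::read.csv))
  })
  de <- tryFile(file.path(dir, "de_results.tsv"), readDEResults)
  network <- tryFile(file.path(dir, "network.tsv"), readRegulatorNetwork)
  list(subjects = subjects, de = de, network = network,
       groundTruth = tryFile(file.path(dir, "ground_truth.json"),
                             jsonlite::read_json),
       config = NULL)
}
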