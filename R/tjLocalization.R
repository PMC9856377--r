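#' @include AllGenerics.R
NULL

#' Tricellular over bicellular junction intensity ratio
#'
#' The tricellulin delocalization statistic: intensity at the tricellular
#' meeting point (tTJ anchor) divided by the bicellular junction intensity
#' read 2 um away along the junction. The bTJ reading is the mean of the
#' two positions anchor - 2 um and anchor + 2 um when both lie inside the
#' profile, otherwise the single available side (the result is then flagged
#' via the "one-sided" attribute). Sub-sample positions are linearly
#' interpolated. Low ratios indicate that tricellulin has been sorted out
#' of the tTJ into the bTJ.
#'
#' @param profile an [IntensityProfile-class].
#' @param btjDistance distance of the bicellular reference, um.
#' @param localMaxRadius if > 0, the tTJ reading is the maximum intensity
#'   within this radius (um) of the anchor instead of the anchor-position
#'   value.
#' @param ... unused.
#' @return The ratio (> 0), with attribute \code{oneSided} (logical).
#' @examples
#' p <- simulateIntensityProfile(enrichment = 3, noiseSd = 0)
#' ttjBtjRatio(p)  # ~ 3
#' @export
setMethod("ttjBtjRatio", "IntensityProfile",
  function(profile, btjDistance = 2, localMaxRadius = 0, ...) {
    pos <- profile@positions
    int <- profile@intensities
    a <- profile@ttjAnchor
    readAt <- function(x) stats::approx(pos, int, xout = x)$y
    ttj <- if (localMaxRadius > 0) {
      inWin <- abs(pos - a) <= localMaxRadius
      max(int[inWin], readAt(a))
    } else readAt(a)
    sides <- c(a - btjDistance, a + btjDistance)
    inside <- sides >= min(pos) & sides <= max(pos)
    if (!any(inside))
      stop("anchor is closer than ", btjDistance, " um to both profile ",
           "ends; no bicellular reference available", call. = FALSE)
    btj <- mean(vapply(sides[inside], readAt, numeric(1)))
    if (!is.finite(btj) || btj <= 0)
      stop("bicellular reference intensity is not positive (",
           format(btj), ")", call. = FALSE)
    structure(ttj / btj, oneSided = sum(inside) == 1L)
  })

#' Aggregate per-measurement ratios into a subject summary
#'
#' The measurement scheme takes several line profiles in each of several
#' tissue sections per subject. The default subject-level statistic is the
#' flat mean over all measurements; per-section means and their average are
#' also stored so the alternative (section-balanced) aggregation can be
#' inspected. Downstream group comparisons use one value per subject.
#'
#' @param ratios numeric per-measurement tTJ/bTJ ratios (> 0).
#' @param sections section identifier per measurement (defaults to a single
#'   section).
#' @param subjectId subject identifier.
#' @return A [TricellularRatio-class].
#' @examples
#' aggregateSubject(c(1, 1, 1, 1, 3, 3), sections = c(1, 1, 1, 1, 2, 2))
#' @export
aggregateSubject <- function(ratios, sections = NULL,
                             subjectId = NA_character_) {
  ratios <- as.numeric(ratios)
  if (!length(ratios) || any(!is.finite(ratios)))
    stop("at least one finite ratio is required", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  sections <- if (is.null(sections)) rep("s1", length(ratios))
              else as.character(sections)
  if (length(sections) != length(ratios))
    stop("sections must match ratios in length", call. = FALSE)
  secMeans <- tapply(ratios, sections, mean)
  new("TricellularRatio", ratios = ratios, sections = sections,
      sectionMeans = c(secMeans), subjectMean = mean(ratios),
      subjectMeanBySection = mean(secMeans),
      nMeasurements = length(ratios), subjectId = as.character(subjectId))
}
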