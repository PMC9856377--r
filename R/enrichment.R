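# Upstream-regulator statistics over a differential-expression results table
# and a signed regulator -> target network: one-sided Fisher/hypergeometric
# overlap p-value and a sign-concordance activation z-score.

#' Select signed differentially expressed genes
#'
#' Thresholds a DESeq2-style results table on absolute log2 fold change and
#' (adjusted) p-value; each selected gene carries the sign of its fold
#' change.
#'
#' @param table data.frame with columns \code{gene}, \code{log2fc},
#'   \code{pvalue} and (if \code{useAdjusted}) \code{padj}.
#' @param lfcThreshold minimum |log2FC| (>= 0).
#' @param pThreshold maximum (adjusted) p-value.
#' @param useAdjusted use \code{padj} instead of \code{pvalue}.
#' @return Named integer vector of signs (+1/-1), names are gene ids. May
#'   be empty; downstream operations refuse empty selections.
#' @export
selectDEGenes <- function(table, lfcThreshold = 1, pThreshold = 0.05,
                          useAdjusted = TRUE) {
  need <- c("gene", "log2fc", if (useAdjusted) "padj" else "pvalue")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0L) stop("DE results table is empty", call. = FALSE)
  .assertScalar(lfcThreshold, "lfcThreshold", nonNegative = TRUE)
  .assertScalar(pThreshold, "pThreshold", nonNegative = TRUE)
  if (anyDuplicated(table$gene)) stop("gene ids must be unique", call. = FALSE)
  p <- if (useAdjusted) table$padj else table$pvalue
  keep <- !is.na(p) & p <= pThreshold & abs(table$log2fc) >= lfcThreshold
  stats::setNames(as.integer(sign(table$log2fc[keep])), table$gene[keep])
}

#' One-sided overlap p-value (Fisher / hypergeometric tail)
#'
#' Probability of observing at least the seen overlap between the DE gene
#' set and a regulator's target set under random draws from the gene
#' universe: \eqn{P(X \ge k)} with
#' \eqn{X \sim Hypergeom(N, |targets|, |DE|)}. Equivalent to the one-sided
#' Fisher exact test on the 2x2 overlap table.
#'
#' @param deGenes character vector (or named sign vector) of DE genes.
#' @param targets character vector of the regulator's target genes.
#' @param universeSize total number of genes considered (>= size of the
#'   union of the two sets).
#' @return p-value in (0, 1].
#' @examples
#' overlapPvalue(paste0("g", 1:4), paste0("g", c(1:3, 10, 11)), 20)
#' # 155/4845 = 0.03199
#' @export
overlapPvalue <- function(deGenes, targets, universeSize) {
  de <- unique(if (!is.null(names(deGenes)) && length(names(deGenes)))
    names(deGenes) else as.character(deGenes))
  tg <- unique(as.character(targets))
  if (!length(de)) stop("DE gene set is empty", call. = FALSE)
  .assertScalar(universeSize, "universeSize", positive = TRUE)
  if (universeSize < length(union(de, tg)))
    stop("universeSize (", universeSize, ") is smaller than the union of ",
         "the two sets (", length(union(de, tg)), ")", call. = FALSE)
  k <- length(intersect(de, tg))
  stats::phyper(k - 1, m = length(tg), n = universeSize - length(tg),
                k = length(de), lower.tail = FALSE)
}

#' Activation z-score from sign concordance
#'
#' For the targets shared between the DE selection and the regulator's
#' target list, counts predictions that agree with the regulator being
#' activated (observed fold-change sign equals the expected regulation
#' sign) versus those that disagree, and returns
#' \deqn{z = \frac{n_{agree} - n_{disagree}}{\sqrt{n_{agree} + n_{disagree}}}}
#' (unit edge weights). \eqn{z > 0} supports activation, \eqn{z < 0}
#' inhibition; \eqn{|z| \le \sqrt{N}} by construction.
#'
#' @param deSigns named integer vector of observed signs (+1/-1), names are
#'   DE gene ids.
#' @param targetSigns named integer vector of expected regulation signs
#'   under activation, names are target gene ids.
#' @return The z-score, or \code{NA_real_} when no signed target overlaps
#'   the DE selection (undefined, as distinct from z = 0).
#' @examples
#' activationZscore(c(a = 1, b = 1, c = -1), c(a = 1, b = 1, c = -1, d = 1))
#' @export
activationZscore <- function(deSigns, targetSigns) {
  if (is.null(names(deSigns)) || is.null(names(targetSigns)))
    stop("deSigns and targetSigns must be named sign vectors", call. = FALSE)
  shared <- intersect(names(deSigns), names(targetSigns))
  if (!length(shared)) return(NA_real_)
  agree <- sum(deSigns[shared] == targetSigns[shared])
  disagree <- length(shared) - agree
  (agree - disagree) / sqrt(length(shared))
}

#' Rank upstream regulators by overlap significance
#'
#' Computes the overlap p-value and activation z-score for every regulator
#' in the network against one DE selection, and orders the results by
#' overlap p ascending, ties by |z| descending (NA z last), then regulator
#' id.
#'
#' @param table DE results data.frame (see [selectDEGenes()]).
#' @param network named list: \code{network[[regulator]]} is a data.frame
#'   with columns \code{target} and \code{sign} (+1/-1); see
#'   [readRegulatorNetwork()].
#' @param lfcThreshold,pThreshold,useAdjusted DE selection thresholds.
#' @param universeSize gene universe; defaults to the number of genes in
#'   the DE table.
#' @return data.frame with columns \code{regulator}, \code{overlap_p},
#'   \code{z_score}, \code{n_overlap}, \code{n_targets}, sorted as above.
#' @export
rankRegulators <- function(table, network, lfcThreshold = 1,
                           pThreshold = 0.05, useAdjusted = TRUE,
                           universeSize = NULL) {
  de <- selectDEGenes(table, lfcThreshold, pThreshold, useAdjusted)
  if (!length(de))
    stop("DE selection is empty at the given thresholds; nothing to rank",
         call. = FALSE)
  if (is.null(universeSize)) universeSize <- nrow(table)
  rows <- lapply(names(network), function(reg) {
    tg <- network[[reg]]
    if (anyDuplicated(tg$target))
      stop("duplicate target for regulator '", reg, "'", call. = FALSE)
    signs <- stats::setNames(as.integer(tg$sign), tg$target)
    data.frame(
      regulator = reg,
      overlap_p = overlapPvalue(de, tg$target, universeSize),
      z_score = activationZscore(de, signs),
      n_overlap = length(intersect(names(de), tg$target)),
      n_targets = length(tg$target),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  absz <- abs(res$z_score)
  absz[is.na(absz)] <- -Inf  # undefined z ranks after any defined z on ties
  res <- res[order(res$overlap_p, -absz, res$regulator), , drop = FALSE]
  rownames(res) <- NULL
  res
}
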