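#' @include AllGenerics.R
NULL

#' One-path equivalent-circuit impedance model
#'
#' Complex impedance of the lumped epithelial circuit: a series subepithelial
#' resistance in front of a parallel RC element for the epithelium,
#' \deqn{Z(f) = R_{sub} + \frac{R_{epi}}{1 + i\,2\pi f\,R_{epi} C}.}
#' With the sign convention used here (passive capacitive element),
#' \eqn{Im(Z) \le 0}, and the Nyquist locus (\eqn{-Im} vs \eqn{Re}) is a
#' semicircle of diameter \eqn{R_{epi}} whose apex \eqn{-Im = R_{epi}/2}
#' sits at the characteristic frequency \eqn{f_c = 1/(2\pi R_{epi} C)}.
#'
#' @param rSub subepithelial resistance, Ohm.cm2 (> 0).
#' @param rEpi epithelial resistance, Ohm.cm2 (>= 0).
#' @param cap epithelial capacitance, F/cm2 (> 0).
#' @param freqs frequencies, Hz.
#' @return Complex impedance, one value per frequency.
#' @examples
#' onePathImpedance(10, 90, 3e-6, c(0.01, 589.5, 1e6))
#' @export
onePathImpedance <- function(rSub, rEpi, cap, freqs) {
  .assertScalar(rSub, "rSub", positive = TRUE)
  .assertScalar(rEpi, "rEpi", nonNegative = TRUE)
  .assertScalar(cap, "cap", positive = TRUE)
  rSub + rEpi / (1 + 1i * 2 * pi * freqs * rEpi * cap)
}

#' Default measurement frequency grid
#'
#' 48 log-spaced frequencies spanning 1.3 Hz to 65 kHz, matching the
#' discrete sine-wave frequencies applied by the impedance rig.
#'
#' @param n number of frequencies.
#' @param fMin,fMax grid limits, Hz.
#' @return Numeric vector of frequencies, Hz, ascending.
#' @export
defaultFrequencyGrid <- function(n = 48L, fMin = 1.3, fMax = 65000) {
  exp(seq(log(fMin), log(fMax), length.out = n))
}

#' Subtract the bathing-solution resistance from a spectrum
#'
#' The bath contributes a pure series resistance; correction subtracts
#' \code{rBath} from the real part at every frequency and leaves the
#' imaginary part untouched. A spectrum can only be corrected once.
#'
#' @param spec an [ImpedanceSpectrum-class].
#' @param rBath bath resistance, Ohm.cm2 (>= 0). Must not exceed the
#'   smallest real part of the spectrum (that would imply a negative tissue
#'   resistance).
#' @return The corrected [ImpedanceSpectrum-class] with
#'   \code{bathCorrected = TRUE}.
#' @export
setMethod("correctBathResistance", "ImpedanceSpectrum", function(spec, rBath) {
  .assertScalar(rBath, "rBath", nonNegative = TRUE)
  if (spec@bathCorrected)
    stop("spectrum is already bath-corrected", call. = FALSE)
  if (rBath > min(Re(spec@z)))
    stop("rBath (", format(rBath), ") exceeds the minimum real impedance (",
         format(min(Re(spec@z))), "); correction would give a negative ",
         "resistance", call. = FALSE)
  ImpedanceSpectrum(spec@freqs, complex(real = Re(spec@z) - rBath,
                                        imaginary = Im(spec@z)),
                    bathCorrected = TRUE, specimenId = spec@specimenId)
})

# Data-driven starting values: rSub from the high-frequency end, rT from the
# low-frequency end, capacitance from the apex of -Im(Z).
.onePathInit <- function(freqs, z) {
  n <- length(freqs)
  rSub0 <- max(Re(z)[n], 1e-6)
  rT0 <- Re(z)[1]
  rEpi0 <- max(rT0 - rSub0, 1e-6)
  fApex <- freqs[which.max(-Im(z))]
  cap0 <- 1 / (2 * pi * fApex * rEpi0)
  c(rSub = rSub0, rEpi = rEpi0, cap = cap0)
}

#' Fit the one-path circuit model to an impedance spectrum
#'
#' Joint least squares on the real and imaginary parts of
#' [onePathImpedance()] over all frequencies, with unweighted residuals.
#' Parameters are optimized on the log scale (Levenberg-Marquardt), which
#' enforces positivity without constraints. Starting values default to
#' end-intercepts and the apex frequency of \eqn{-Im(Z)}.
#'
#' \code{method = "intercept"} instead reads the resistances off the
#' frequency ends as in classical practice: \eqn{R_t} is the mean real part
#' over the 3 lowest frequencies and \eqn{R_{sub}} over the 3 highest; the
#' capacitance still comes from the apex frequency.
#'
#' @param spec an [ImpedanceSpectrum-class] with at least 8 frequencies
#'   spanning at least two decades. A warning is issued when the spectrum is
#'   not flagged bath-corrected.
#' @param init optional named starting values \code{c(rSub, rEpi, cap)}.
#' @param method "fit" (default, full complex least squares) or "intercept".
#' @param nEnd number of frequencies defining each end for the intercept
#'   method.
#' @param ... unused.
#' @return A [OnePathFit-class]. Non-convergence is reported through the
#'   \code{converged} flag, not an error.
#' @examples
#' f <- defaultFrequencyGrid()
#' sp <- ImpedanceSpectrum(f, onePathImpedance(12, 25, 3e-6, f),
#'                         bathCorrected = TRUE)
#' fitOnePath(sp)
#' @export
setMethod("fitOnePath", "ImpedanceSpectrum",
  function(spec, init = NULL, method = c("fit", "intercept"), nEnd = 3L, ...) {
    method <- match.arg(method)
    freqs <- spec@freqs
    z <- spec@z
    if (length(freqs) < 8L)
      stop("at least 8 frequencies are required for a one-path fit",
           call. = FALSE)
    if (log10(max(freqs) / min(freqs)) < 2)
      stop("frequency grid must span at least two decades", call. = FALSE)
    if (!spec@bathCorrected)
      warning("spectrum is not flagged bath-corrected; fitting as-is")
    if (max(abs(Im(z))) <= 1e-9 * max(abs(Re(z))))
      stop("spectrum has no reactive component (all Im(Z) ~ 0); ",
           "rEpi is ~ 0 and the RC element is unidentifiable", call. = FALSE)

    if (method == "intercept") {
      nEnd <- min(nEnd, length(freqs))
      rTh <- mean(Re(z)[seq_len(nEnd)])
      rSubh <- mean(Re(z)[seq(length(z) - nEnd + 1L, length(z))])
      rEpih <- max(rTh - rSubh, 0)
      fApex <- freqs[which.max(-Im(z))]
      caph <- 1 / (2 * pi * fApex * max(rEpih, 1e-12))
      resid <- c(Re(onePathImpedance(rSubh, rEpih, caph, freqs) - z),
                 Im(onePathImpedance(rSubh, rEpih, caph, freqs) - z))
      return(.OnePathFit(rSubh, rEpih, caph, sqrt(sum(resid^2)),
                         converged = TRUE, method = "intercept",
                         specimenId = spec@specimenId))
    }

    start <- if (is.null(init)) .onePathInit(freqs, z)
             else c(rSub = init[["rSub"]], rEpi = init[["rEpi"]],
                    cap = init[["cap"]])
    residFun <- function(logPar) {
      p <- exp(logPar)
      zm <- onePathImpedance(p[1], p[2], p[3], freqs)
      c(Re(zm - z), Im(zm - z))
    }
    fit <- minpack.lm::nls.lm(
      par = log(start), fn = residFun,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 500))
    p <- exp(fit$par)
    .OnePathFit(unname(p[1]), unname(p[2]), unname(p[3]),
                residualNorm = sqrt(sum(fit$fvec^2)),
                converged = fit$info %in% 1:4, method = "fit",
                specimenId = spec@specimenId)
  })

#' Epithelial resistance by subtraction
#'
#' \eqn{R_{epi} = R_t - R_{sub}}: the transmural resistance minus the
#' subepithelial series contribution.
#'
#' @param rT transmural resistance, Ohm.cm2.
#' @param rSub subepithelial resistance, Ohm.cm2 (\code{rT >= rSub >= 0}).
#' @return Epithelial resistance, Ohm.cm2.
#' @examples
#' epithelialResistance(120, 30)  # 90
#' @export
epithelialResistance <- function(rT, rSub) {
  .assertScalar(rT, "rT", nonNegative = TRUE)
  .assertScalar(rSub, "rSub", nonNegative = TRUE)
  if (rT < rSub)
    stop("rT (", format(rT), ") must be >= rSub (", format(rSub), ")",
         call. = FALSE)
  rT - rSub
}
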