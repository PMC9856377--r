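#' @include AllGenerics.R
NULL

# interpolated Isc reading at an arbitrary time; prefers the nearest sample
# within `tol` minutes, falls back to linear interpolation
.iscAt <- function(trace, t, tol = 1) {
  i <- which.min(abs(trace@time - t))
  if (abs(trace@time[i] - t) <= tol) return(trace@isc[i])
  stats::approx(trace@time, trace@isc, xout = t)$y
}

.eventTime <- function(trace, drug) {
  ev <- trace@events
  hit <- ev$time_min[ev$drug == drug]
  if (length(hit) != 1L)
    stop("trace has no '", drug, "' event", call. = FALSE)
  hit
}

#' Baseline short-circuit current
#'
#' Mean Isc over the pre-event window: all samples strictly before the first
#' drug addition (the whole trace when there are no events).
#'
#' @param trace an [IscTrace-class].
#' @param ... unused.
#' @return Baseline Isc, uA/cm2.
#' @examples
#' tr <- IscTrace(0:10, rep(100, 11))
#' baselineIsc(tr)  # 100
#' @export
setMethod("baselineIsc", "IscTrace", function(trace, ...) {
  tFirst <- if (nrow(trace@events)) min(trace@events$time_min) else Inf
  pre <- trace@isc[trace@time < tFirst]
  if (length(pre) < 2L)
    stop("need at least 2 samples before the first event to define a ",
         "baseline", call. = FALSE)
  mean(pre)
})

#' Bumetanide-sensitive chloride secretion
#'
#' Quantifies active electrogenic anion secretion as the difference between
#' the maximum Isc before serosal bumetanide and the Isc 20 min after its
#' addition. The post-drug reading takes the nearest sample within
#' \code{tol} minutes of the +20 min mark, else linear interpolation.
#'
#' @param trace an [IscTrace-class] containing a "bumetanide" event, with
#'   at least 20 min of recording after it.
#' @param postMin minutes after the addition at which the post-drug value is
#'   read (20 by default).
#' @param tol nearest-sample tolerance, minutes.
#' @param ... unused.
#' @return A [DrugResponse-class]; \code{deltaIsc = preValue - postValue}.
#' @export
setMethod("bumetanideResponse", "IscTrace",
  function(trace, postMin = 20, tol = 1, ...) {
    t0 <- .eventTime(trace, "bumetanide")
    if (max(trace@time) < t0 + postMin)
      stop("trace must extend at least ", postMin, " min past the ",
           "bumetanide addition (ends ",
           format(max(trace@time) - t0, digits = 4), " min after it)",
           call. = FALSE)
    pre <- max(trace@isc[trace@time < t0])
    post <- .iscAt(trace, t0 + postMin, tol = tol)
    .DrugResponse("bumetanide", preValue = pre, postValue = post,
                  window = c(t0 + postMin, t0 + postMin))
  })

#' Amiloride-sensitive electrogenic sodium absorption
#'
#' ENaC-mediated sodium transport is read as the drop in Isc after mucosal
#' amiloride in aldosterone-stimulated tissue: the mean of the last
#' \code{nPre} samples before the addition minus the mean over the
#' \code{postWindow} (minutes after addition, default 5-15 min). A negative
#' response is returned signed and flagged rather than truncated.
#'
#' @param trace an [IscTrace-class] containing an "amiloride" event. An
#'   "aldosterone" annotation event may be present; it is informational only.
#' @param nPre number of pre-event plateau samples.
#' @param postWindow length-2 numeric, minutes after the addition.
#' @param ... unused.
#' @return A [DrugResponse-class].
#' @export
setMethod("amilorideJNa", "IscTrace",
  function(trace, nPre = 5L, postWindow = c(5, 15), ...) {
    t0 <- .eventTime(trace, "amiloride")
    preIdx <- which(trace@time < t0)
    if (!length(preIdx))
      stop("no samples before the amiloride addition", call. = FALSE)
    preIdx <- utils::tail(preIdx, nPre)
    pre <- mean(trace@isc[preIdx])
    postIdx <- which(trace@time >= t0 + postWindow[1] &
                     trace@time <= t0 + postWindow[2])
    if (!length(postIdx))
      stop("no samples in the post-amiloride window [",
           postWindow[1], ", ", postWindow[2], "] min after the addition",
           call. = FALSE)
    post <- mean(trace@isc[postIdx])
    flags <- if (pre - post < 0) "negative-response" else character()
    .DrugResponse("amiloride", preValue = pre, postValue = post,
                  window = t0 + postWindow, flags = flags)
  })

#' Convert a short-circuit current change to a molar flux
#'
#' Standard electrophysiological conversion via the Faraday constant:
#' a current density of 1 uA/cm2 carried by a monovalent ion corresponds to
#' \eqn{1 \times 10^{-6} \cdot 3600 / 96485} mol/h/cm2 = 0.0373 umol/h/cm2.
#'
#' @param deltaIsc current change, uA/cm2 (signed).
#' @param charge elementary charges per transported ion (non-zero; sign
#'   allowed).
#' @return Flux, umol/h/cm2 (sign-preserving, linear in \code{deltaIsc}).
#' @examples
#' iscToMolarFlux(1, 1)       # 0.0373
#' iscToMolarFlux(96.485, 1)  # 3.6
#' @export
iscToMolarFlux <- function(deltaIsc, charge = 1) {
  .assertScalar(charge, "charge")
  if (charge == 0) stop("charge must be non-zero", call. = FALSE)
  # uA -> A (1e-6), C/s -> mol/h (3600 / zF), mol -> umol (1e6): the 1e-6
  # and 1e6 cancel
  deltaIsc * 3600 / (charge * 96485)
}
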