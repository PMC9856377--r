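#' Mucosal-to-serosal surface area ratio from crypt geometry
#'
#' Models each crypt as a right circular cylinder opening onto a flat
#' reference plane. Per cm2 of serosal area, the mucosal surface is the
#' plane minus the crypt openings plus the cylindrical crypt walls plus the
#' crypt bottoms; with flat bottoms the openings and bottoms cancel and
#' \deqn{ratio = 1 + n\,\pi\,d\,L,} with the inner diameter \eqn{d} and
#' crypt length \eqn{L} in cm and the crypt density \eqn{n} in cm^-2.
#' Hemispherical bottoms add a further \eqn{n\,\pi\,d^2/4}.
#'
#' @param innerDiameterUm inner crypt diameter, um.
#' @param cryptLengthUm crypt length, um.
#' @param cryptDensityPerCm2 crypts per cm2 of serosal area.
#' @param bottom crypt bottom shape, "flat" (default) or "hemisphere".
#' @return Dimensionless surface amplification ratio (>= 1).
#' @examples
#' surfaceRatio(50, 400, 5700)  # 4.58
#' @export
surfaceRatio <- function(innerDiameterUm, cryptLengthUm, cryptDensityPerCm2,
                         bottom = c("flat", "hemisphere")) {
  bottom <- match.arg(bottom)
  .assertScalar(innerDiameterUm, "innerDiameterUm", positive = TRUE)
  .assertScalar(cryptLengthUm, "cryptLengthUm", positive = TRUE)
  .assertScalar(cryptDensityPerCm2, "cryptDensityPerCm2", nonNegative = TRUE)
  d <- innerDiameterUm * 1e-4
  L <- cryptLengthUm * 1e-4
  n <- cryptDensityPerCm2
  openings <- n * pi * (d / 2)^2
  if (openings > 1)
    stop("crypt openings (", format(openings), " cm2 per cm2) exceed the ",
         "serosal reference plane; geometry is inconsistent", call. = FALSE)
  r <- 1 + n * pi * d * L
  if (bottom == "hemisphere") r <- r + n * pi * d^2 / 4
  r
}

#' Epithelial apoptosis rate from nucleus counts
#'
#' Percentage of TUNEL-positive (apoptotic) nuclei among all DAPI-positive
#' nuclei.
#'
#' @param apoptotic apoptotic nucleus count.
#' @param totalDapi total DAPI-positive nucleus count (> 0, >= apoptotic).
#' @return Apoptosis rate, percent.
#' @examples
#' apoptosisRate(3, 300)  # 1
#' @export
apoptosisRate <- function(apoptotic, totalDapi) {
  .assertScalar(apoptotic, "apoptotic", nonNegative = TRUE)
  .assertScalar(totalDapi, "totalDapi", positive = TRUE)
  if (apoptotic > totalDapi)
    stop("apoptotic count exceeds total DAPI-positive count", call. = FALSE)
  100 * apoptotic / totalDapi
}
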