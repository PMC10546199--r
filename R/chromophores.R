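## Hemoglobin extinction coefficients and the absorption convention used
## throughout the package:
##
##   mua [mm^-1] = ln(10) * sum_j eps_j[cm^-1/M] * 1e-7 * C_j[uM]
##
## (1 cm^-1/M = 0.1 mm^-1/M = 1e-7 mm^-1/uM). The molar extinction values
## below are approximate compiled whole-blood hemoglobin spectra (Prahl-style
## tabulation, cm^-1/M); every chromophore computation in the package goes
## through this single table, so concentration round-trips are exact by
## construction regardless of the absolute accuracy of the tabulation.

.HB_EXTINCTION <- data.frame(
  wavelength = c(633, 660, 780, 850),
  hbo2 = c(350.0, 319.6, 740.0, 1058.0),   # oxyhemoglobin, cm^-1/M
  hbr = c(4700.0, 3226.56, 1100.0, 691.3)  # deoxyhemoglobin, cm^-1/M
)

#' Hemoglobin extinction matrix
#'
#' Returns the extinction matrix E (rows: wavelengths; columns: HbO2, HbR)
#' in mm^-1 per uM, including the ln(10) factor, so that
#' \code{mua = E \%*\% c(C_HbO2, C_HbR)} with concentrations in uM gives
#' absorption in mm^-1.
#'
#' @param wavelengths wavelengths, nm; must be among the tabulated
#'   633/660/780/850 nm.
#' @return numeric matrix with columns \code{HbO2} and \code{HbR}.
#' @examples
#' extinctionMatrix(c(660, 780, 850))
#' @export
extinctionMatrix <- function(wavelengths = c(660, 780, 850)) {
  i <- match(wavelengths, .HB_EXTINCTION$wavelength)
  if (anyNA(i))
    stop("untabulated wavelength(s): ",
         paste(wavelengths[is.na(i)], collapse = ", "))
  E <- log(10) * 1e-7 *
    cbind(HbO2 = .HB_EXTINCTION$hbo2[i], HbR = .HB_EXTINCTION$hbr[i])
  rownames(E) <- as.character(wavelengths)
  E
}

#' Absorption map at a wavelength from chromophore concentrations
#'
#' Forward application of the extinction convention:
#' \eqn{\mu_a(\lambda) = \ln 10\,(\epsilon_{HbO2}(\lambda) C_{HbO2} +
#' \epsilon_{HbR}(\lambda) C_{HbR})}, used to transfer SFDI-derived
#' hemoglobin concentrations to the LSI wavelength (633 nm).
#'
#' @param chrom a \linkS4class{ChromophoreMap}.
#' @param wavelength target wavelength, nm (default 633).
#' @param eps optional 1 x 2 extinction row (mm^-1/uM, ln 10 included)
#'   overriding the built-in tabulation.
#' @return absorption map, mm^-1.
#' @export
muaAtWavelength <- function(chrom, wavelength = 633, eps = NULL) {
  stopifnot(is(chrom, "ChromophoreMap"))
  if (is.null(eps)) eps <- extinctionMatrix(wavelength)
  stopifnot(length(eps) == 2L)
  eps <- as.numeric(eps)
  eps[1] * chrom@cHbO2 + eps[2] * chrom@cHbR
}
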