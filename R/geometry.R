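## Field-of-view and speckle-sampling arithmetic for the imaging geometry:
## a 10 x 10 mm field imaged at 1200 x 1200 pixels (8.33 um/px on the
## sample) through an f/4 lens at magnification 0.42.

#' Convert a pixel distance to millimetres on the sample
#'
#' @param px distance in pixels.
#' @param fovMm field-of-view side length, mm (default 10).
#' @param fovPx field-of-view side length, pixels (default 1200).
#' @return distance in mm (e.g. a 200 px ROI radius is about 1.6 mm).
#' @export
pixelsToMm <- function(px, fovMm = 10, fovPx = 1200) {
  stopifnot(fovMm > 0, fovPx > 0)
  px * fovMm / fovPx
}

#' Minimum speckle diameter on the detector
#'
#' Diffraction-limited speckle size for a polarized imaging system,
#' \eqn{d = 2.44\,\lambda\,(1 + M)\,f_\#} (um): about 9 um at 632.8 nm,
#' magnification 0.42 and f/4, versus a 3.45 um camera pixel — the
#' speckle-to-pixel size ratio that the beta factor absorbs.
#'
#' @param wavelengthNm illumination wavelength, nm (default 632.8).
#' @param magnification imaging magnification M (default 0.42).
#' @param fNumber lens f-number (default 4).
#' @return speckle diameter, um.
#' @export
speckleDiameterUm <- function(wavelengthNm = 632.8, magnification = 0.42,
                              fNumber = 4) {
  2.44 * (wavelengthNm * 1e-3) * (1 + magnification) * fNumber
}
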