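#' Extract the principal pixel matrix of a map object
#'
#' Returns the underlying numeric matrix of a map-like object: the amplitude
#' of a \linkS4class{DemodulatedMap}, the reflectance of an
#' \linkS4class{RdMap}, the contrast of a \linkS4class{ContrastMap} or the
#' flow values of a \linkS4class{FlowMap}.
#'
#' @param x a map object.
#' @return a numeric matrix (NA at invalid pixels where applicable).
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Logical mask of invalid pixels
#' @param x an object carrying an invalid-pixel mask.
#' @return a logical matrix.
#' @export
setGeneric("invalidMask", function(x) standardGeneric("invalidMask"))

#' Absorption coefficient accessor (mm^-1)
#' @param x an object with absorption information.
#' @return numeric vector or matrix.
#' @export
setGeneric("mua", function(x) standardGeneric("mua"))

#' Reduced scattering coefficient accessor (mm^-1)
#' @param x an object with scattering information.
#' @return numeric vector or matrix.
#' @export
setGeneric("musp", function(x) standardGeneric("musp"))

#' Wavelength accessor (nm)
#' @param x an object with a wavelength.
#' @return numeric.
#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))

setMethod("mapValues", "DemodulatedMap", function(x) x@mac)
setMethod("mapValues", "RdMap", function(x) x@rd)
setMethod("mapValues", "ContrastMap", function(x) x@k)
setMethod("mapValues", "FlowMap", function(x) x@values)

setMethod("invalidMask", "ContrastMap", function(x) x@invalid)
setMethod("invalidMask", "FlowMap", function(x) x@invalid)
setMethod("invalidMask", "OpticalPropertyMap", function(x) x@invalid)

setMethod("mua", "OpticalProperties", function(x) x@mua)
setMethod("mua", "OpticalPropertyMap", function(x) x@mua)
setMethod("musp", "OpticalProperties", function(x) x@musp)
setMethod("musp", "OpticalPropertyMap", function(x) x@musp)
setMethod("wavelength", "OpticalProperties", function(x) x@wavelength)
setMethod("wavelength", "OpticalPropertyMap", function(x) x@wavelength)

setMethod("show", "OpticalProperties", function(object) {
  cat("OpticalProperties:", length(object@wavelength), "wavelength(s)\n")
  for (i in seq_along(object@wavelength))
    cat(sprintf("  %g nm: mua = %.4g mm^-1, musp = %.4g mm^-1\n",
                object@wavelength[i], object@mua[i], object@musp[i]))
})

setMethod("show", "BoundaryTerms", function(object) {
  cat(sprintf("BoundaryTerms: n = %.3f, Reff = %.5f, A = %.5f\n",
              object@n, object@reff, object@a))
})

setMethod("show", "ContrastMap", function(object) {
  cat(sprintf("ContrastMap: %d x %d, window %d px, T = %g s, %d invalid px\n",
              nrow(object@k), ncol(object@k), as.integer(object@window),
              object@exposure, sum(object@invalid)))
  k <- object@k[!object@invalid]
  if (length(k)) cat(sprintf("  K: median %.4f [%.4f, %.4f]\n",
                             stats::median(k), min(k), max(k)))
})

setMethod("show", "FlowMap", function(object) {
  unit <- if (object@kind == "db") "mm^2/s" else "s^-1"
  v <- object@values[!object@invalid]
  cat(sprintf("FlowMap (%s): %d x %d, %d invalid px\n", object@kind,
              nrow(object@values), ncol(object@values), sum(object@invalid)))
  if (length(v)) cat(sprintf("  median %.4g %s\n", stats::median(v), unit))
})

setMethod("show", "OpticalPropertyMap", function(object) {
  ok <- !object@invalid
  cat(sprintf("OpticalPropertyMap @ %g nm: %d x %d, %d invalid px\n",
              object@wavelength, nrow(object@mua), ncol(object@mua),
              sum(object@invalid)))
  if (any(ok))
    cat(sprintf("  mua median %.4g, musp median %.4g mm^-1\n",
                stats::median(object@mua[ok]), stats::median(object@musp[ok])))
})

setMethod("show", "RdLut", function(object) {
  cat(sprintf("RdLut: %d x %d grid, mua [%g, %g], musp [%g, %g] mm^-1, fxAC = %g, n = %g\n",
              length(object@muaAxis), length(object@muspAxis),
              min(object@muaAxis), max(object@muaAxis),
              min(object@muspAxis), max(object@muspAxis),
              object@fxAc, object@n))
})

setMethod("show", "K2Lut", function(object) {
  cat(sprintf("K2Lut: %d x %d x %d (Db x mua x musp), Db <= %g mm^2/s, beta = %g, T = %g s, %g nm\n",
              length(object@dbAxis), length(object@muaAxis),
              length(object@muspAxis), max(object@dbAxis),
              object@beta, object@exposure, object@wavelength))
})

setMethod("show", "CycleSchedule", function(object) {
  cat(sprintf("CycleSchedule: 18 slots @ %g Hz (cycle %.3f s)\n",
              object@rawRate, 18 / object@rawRate))
  print(utils::head(object@entries, 6))
  cat("  ...\n")
})

setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene '%s': %d x %d px, wavelengths %s nm, Db in [%g, %g] mm^2/s\n",
              object@name, object@dims[1], object@dims[2],
              paste(object@wavelengths, collapse = "/"),
              min(object@db), max(object@db)))
})
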