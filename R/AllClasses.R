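#' @import methods
NULL

## Central S4 containers for the LSI/SFDI processing stack. All lengths are
## in mm internally; wavelengths are carried in nm and converted to mm only
## when a wavenumber is formed. Concentrations are in uM, exposure times in
## seconds.

#' Tissue optical properties at one or more wavelengths
#'
#' Holds absorption (\code{mua}) and reduced scattering (\code{musp})
#' coefficients, both in mm^-1, at the stated wavelengths (nm). Vectors of
#' equal length describe one medium at several wavelengths.
#'
#' @slot mua absorption coefficient(s), mm^-1, strictly positive.
#' @slot musp reduced scattering coefficient(s), mm^-1, strictly positive.
#' @slot wavelength wavelength(s), nm.
#' @export
setClass("OpticalProperties",
  representation(mua = "numeric", musp = "numeric", wavelength = "numeric"),
  validity = function(object) {
    n <- length(object@mua)
    if (length(object@musp) != n || length(object@wavelength) != n)
      return("mua, musp and wavelength must have equal length")
    if (n == 0L) return("at least one wavelength is required")
    if (any(!is.finite(object@mua)) || any(object@mua <= 0))
      return("mua must be finite and > 0")
    if (any(!is.finite(object@musp)) || any(object@musp <= 0))
      return("musp must be finite and > 0")
    if (any(object@wavelength <= 0)) return("wavelength must be > 0")
    TRUE
  })

#' Diffusion boundary terms for a refractive-index-mismatched interface
#'
#' @slot n refractive index of the medium.
#' @slot reff effective reflection coefficient (dimensionless).
#' @slot a boundary coefficient A (dimensionless), in (0, 0.5].
#' @export
setClass("BoundaryTerms",
  representation(n = "numeric", reff = "numeric", a = "numeric"),
  validity = function(object) {
    if (object@reff < 0 || object@reff >= 1) return("reff must be in [0, 1)")
    if (object@a <= 0 || object@a > 0.5) return("a must be in (0, 0.5]")
    TRUE
  })

#' Three-phase SFDI frame triplet at one spatial frequency and wavelength
#'
#' @slot i1,i2,i3 intensity images (counts) at phases 0, 120 and 240 degrees.
#' @slot fx spatial frequency, mm^-1.
#' @slot wavelength wavelength, nm.
#' @export
setClass("PhaseTriplet",
  representation(i1 = "matrix", i2 = "matrix", i3 = "matrix",
                 fx = "numeric", wavelength = "numeric"),
  validity = function(object) {
    d <- dim(object@i1)
    if (!identical(d, dim(object@i2)) || !identical(d, dim(object@i3)))
      return("phase images must share dimensions")
    if (min(object@i1, object@i2, object@i3) < 0)
      return("intensities must be non-negative")
    if (object@fx < 0) return("fx must be >= 0")
    TRUE
  })

#' Demodulated SFDI amplitude map
#'
#' AC amplitude (or, for fx = 0, planar DC amplitude) extracted from a
#' \linkS4class{PhaseTriplet}.
#'
#' @slot mac amplitude image (counts), non-negative.
#' @slot fx spatial frequency, mm^-1.
#' @slot wavelength wavelength, nm.
#' @slot smoothed whether Gaussian smoothing has been applied.
#' @export
setClass("DemodulatedMap",
  representation(mac = "matrix", fx = "numeric", wavelength = "numeric",
                 smoothed = "logical"),
  validity = function(object) {
    if (min(object@mac, na.rm = TRUE) < 0) return("mac must be >= 0")
    TRUE
  })

#' Calibrated diffuse reflectance map
#'
#' @slot rd diffuse reflectance image (dimensionless), >= 0.
#' @slot fx spatial frequency, mm^-1.
#' @slot wavelength wavelength, nm.
#' @export
setClass("RdMap",
  representation(rd = "matrix", fx = "numeric", wavelength = "numeric"),
  validity = function(object) {
    if (min(object@rd, na.rm = TRUE) < 0) return("rd must be >= 0")
    TRUE
  })

#' Forward diffuse-reflectance lookup table over (mua, musp)
#'
#' Rd grids at the two measurement spatial frequencies, evaluated with the
#' semi-infinite spatial-frequency-domain diffusion forward model.
#'
#' @slot muaAxis mua grid nodes, mm^-1 (linearly spaced).
#' @slot muspAxis musp grid nodes, mm^-1 (linearly spaced).
#' @slot rd0,rd03 Rd grids (rows: mua, cols: musp) at fx = 0 and the AC
#'   frequency.
#' @slot fxAc the AC spatial frequency, mm^-1 (default 0.3).
#' @slot n refractive index used for the forward model.
#' @export
setClass("RdLut",
  representation(muaAxis = "numeric", muspAxis = "numeric",
                 rd0 = "matrix", rd03 = "matrix",
                 fxAc = "numeric", n = "numeric"),
  validity = function(object) {
    dm <- c(length(object@muaAxis), length(object@muspAxis))
    if (!identical(dim(object@rd0), dm) || !identical(dim(object@rd03), dm))
      return("rd grids must be length(muaAxis) x length(muspAxis)")
    if (min(object@rd0, object@rd03) <= 0 || max(object@rd0, object@rd03) >= 1)
      return("Rd values must lie in (0, 1)")
    TRUE
  })

#' Per-pixel optical property maps at one wavelength
#'
#' @slot mua,musp per-pixel coefficient maps, mm^-1 (NA where invalid).
#' @slot wavelength wavelength, nm.
#' @slot invalid logical mask of pixels outside the attainable reflectance
#'   region (or otherwise unrecoverable).
#' @export
setClass("OpticalPropertyMap",
  representation(mua = "matrix", musp = "matrix", wavelength = "numeric",
                 invalid = "matrix"),
  validity = function(object) {
    d <- dim(object@mua)
    if (!identical(d, dim(object@musp)) || !identical(d, dim(object@invalid)))
      return("mua, musp and invalid must share dimensions")
    if (!is.logical(object@invalid)) return("invalid must be logical")
    ok <- !object@invalid
    if (any(ok & (is.na(object@mua) | is.na(object@musp))))
      return("valid pixels must carry finite mua and musp")
    TRUE
  })

#' Hemoglobin chromophore maps
#'
#' Oxy-/deoxy-hemoglobin concentrations (uM), total hemoglobin and oxygen
#' saturation derived from multi-wavelength absorption maps.
#'
#' @slot cHbO2,cHbR concentration maps, uM.
#' @slot hbt total hemoglobin, uM (\code{cHbO2 + cHbR} pixelwise).
#' @slot sto2 oxygen saturation, percent (NA where hbt <= 0).
#' @export
setClass("ChromophoreMap",
  representation(cHbO2 = "matrix", cHbR = "matrix",
                 hbt = "matrix", sto2 = "matrix"),
  validity = function(object) {
    d <- dim(object@cHbO2)
    if (!identical(d, dim(object@cHbR)) || !identical(d, dim(object@hbt)) ||
        !identical(d, dim(object@sto2)))
      return("all maps must share dimensions")
    if (max(abs(object@hbt - (object@cHbO2 + object@cHbR)), na.rm = TRUE) > 1e-9)
      return("hbt must equal cHbO2 + cHbR pixelwise")
    TRUE
  })

#' Spatial speckle contrast map
#'
#' @slot k contrast image K = sd/mean over a sliding window (NA on the
#'   border and at invalid pixels).
#' @slot exposure camera exposure time T, seconds.
#' @slot window sliding-window side length, pixels (odd).
#' @slot invalid logical mask (border and zero-mean windows).
#' @export
setClass("ContrastMap",
  representation(k = "matrix", exposure = "numeric", window = "numeric",
                 invalid = "matrix"),
  validity = function(object) {
    if (object@exposure <= 0) return("exposure must be > 0")
    w <- object@window
    if (w < 1 || w %% 2 != 1) return("window must be odd and >= 1")
    if (!identical(dim(object@k), dim(object@invalid)))
      return("k and invalid must share dimensions")
    if (min(object@k, na.rm = TRUE) < 0) return("k must be >= 0")
    TRUE
  })

#' Speckle normalization factor beta
#'
#' Estimated from a static phantom as the squared speckle contrast; accounts
#' for speckle/pixel size mismatch and polarization.
#'
#' @slot beta the factor, in (0, 1].
#' @slot source free-text identifier of the static phantom measurement.
#' @export
setClass("BetaFactor",
  representation(beta = "numeric", source = "character"),
  validity = function(object) {
    if (object@beta <= 0 || object@beta > 1) return("beta must be in (0, 1]")
    TRUE
  })

#' Per-pixel flow map (SFI or Db)
#'
#' @slot values flow values: s^-1 for \code{kind = "sfi"}, mm^2/s for
#'   \code{kind = "db"}.
#' @slot kind either \code{"sfi"} or \code{"db"}.
#' @slot invalid logical mask of flagged pixels.
#' @export
setClass("FlowMap",
  representation(values = "matrix", kind = "character", invalid = "matrix"),
  validity = function(object) {
    if (!object@kind %in% c("sfi", "db")) return("kind must be 'sfi' or 'db'")
    if (!identical(dim(object@values), dim(object@invalid)))
      return("values and invalid must share dimensions")
    v <- object@values[!object@invalid]
    if (length(v) && min(v, na.rm = TRUE) < 0)
      return("valid flow values must be >= 0")
    TRUE
  })

#' Scattering power-law fit musp(lambda) = amp * (lambda/850)^slope
#'
#' @slot amp scattering amplitude at the 850 nm reference, mm^-1.
#' @slot slope scattering power (dimensionless, typically negative).
#' @slot refWavelength reference wavelength, nm (850).
#' @export
setClass("PowerLawFit",
  representation(amp = "numeric", slope = "numeric", refWavelength = "numeric"),
  validity = function(object) {
    if (object@amp <= 0) return("amp must be > 0")
    TRUE
  })

#' Forward K^2 lookup table over (Db, mua, musp)
#'
#' Exposure-integrated squared speckle contrast predicted by the correlation
#' diffusion equation on a 3-D grid, used to invert measured contrast for Db.
#'
#' @slot dbAxis Db nodes, mm^2/s (linear, starting at 0).
#' @slot muaAxis,muspAxis optical property nodes, mm^-1.
#' @slot k2 array \code{[db, mua, musp]} of K^2 values in (0, beta].
#' @slot beta normalization factor baked into the grid.
#' @slot exposure exposure time T, s.
#' @slot wavelength LSI wavelength, nm.
#' @slot n refractive index.
#' @export
setClass("K2Lut",
  representation(dbAxis = "numeric", muaAxis = "numeric", muspAxis = "numeric",
                 k2 = "array", beta = "numeric", exposure = "numeric",
                 wavelength = "numeric", n = "numeric"),
  validity = function(object) {
    dm <- c(length(object@dbAxis), length(object@muaAxis),
            length(object@muspAxis))
    if (!identical(dim(object@k2), dm))
      return("k2 must be [db x mua x musp]")
    if (object@dbAxis[1] != 0) return("dbAxis must start at 0")
    if (min(object@k2) <= 0 || max(object@k2) > object@beta + 1e-12)
      return("k2 values must lie in (0, beta]")
    TRUE
  })

#' Acquisition cycle schedule (18 frames)
#'
#' The fixed 18-slot ordering of one paired LSI/SFDI acquisition cycle:
#' 3 wavelengths x 2 spatial frequencies x 3 phases, wavelengths cycling
#' fastest.
#'
#' @slot rawRate raw frame rate, Hz.
#' @slot entries data.frame with columns \code{index} (0-17),
#'   \code{wavelength} (nm), \code{fx} (mm^-1), \code{phase} (degrees),
#'   \code{offset_s} (time offset within the cycle).
#' @export
setClass("CycleSchedule",
  representation(rawRate = "numeric", entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    if (nrow(e) != 18L) return("a cycle has exactly 18 slots")
    if (!identical(sort(e$index), 0:17)) return("indices 0-17 must appear once")
    key <- paste(e$wavelength, e$fx, e$phase)
    if (anyDuplicated(key)) return("(wavelength, fx, phase) must be unique")
    if (object@rawRate <= 0) return("rawRate must be > 0")
    TRUE
  })

#' Digital phantom scene with piecewise-constant properties
#'
#' A synthetic scene: per-pixel optical properties at each SFDI wavelength
#' (and the LSI wavelength) plus a per-pixel Brownian diffusion coefficient.
#'
#' @slot dims image dimensions (rows, cols), pixels.
#' @slot wavelengths wavelengths (nm) for which property maps exist.
#' @slot mua,musp lists of per-wavelength coefficient matrices, mm^-1.
#' @slot db per-pixel Brownian diffusion coefficient, mm^2/s (>= 0).
#' @slot name scene identifier.
#' @export
setClass("PhantomScene",
  representation(dims = "integer", wavelengths = "numeric",
                 mua = "list", musp = "list", db = "matrix",
                 name = "character"),
  validity = function(object) {
    nw <- length(object@wavelengths)
    if (length(object@mua) != nw || length(object@musp) != nw)
      return("one mua and musp map per wavelength")
    for (i in seq_len(nw)) {
      if (!identical(dim(object@mua[[i]]), object@dims) ||
          !identical(dim(object@musp[[i]]), object@dims))
        return("property maps must match scene dims")
      if (min(object@mua[[i]]) <= 0 || min(object@musp[[i]]) <= 0)
        return("optical properties must be > 0")
    }
    if (!identical(dim(object@db), object@dims)) return("db must match dims")
    if (min(object@db) < 0) return("db must be >= 0")
    TRUE
  })
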