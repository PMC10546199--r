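## Physics-faithful synthetic raw frames, so every pipeline stage is
## testable without an instrument: fully developed speckle stacks with
## controllable temporal decorrelation, sinusoidally patterned SFDI
## renderings over digital phantom scenes, and the printed phantom library.

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Optical properties of the calibration phantom
#'
#' The reference silicone phantom: mua = 0.019 mm^-1 at all three SFDI
#' wavelengths and musp = 1.07 / 0.83 / 0.72 mm^-1 at 660 / 780 / 850 nm.
#'
#' @return an \linkS4class{OpticalProperties} object.
#' @export
calibrationPhantom <- function() {
  opticalProperties(mua = c(0.019, 0.019, 0.019),
                    musp = c(1.07, 0.83, 0.72),
                    wavelength = c(660, 780, 850))
}

#' Optical properties of the static part of the flow phantom
#'
#' TiO2-in-silicone phantom with no added absorber: mua = 0.0049 / 0.0059 /
#' 0.0062 mm^-1 and musp = 0.87 / 0.67 / 0.60 mm^-1 at 660 / 780 / 850 nm.
#'
#' @return an \linkS4class{OpticalProperties} object.
#' @export
flowPhantomStatic <- function() {
  opticalProperties(mua = c(0.0049, 0.0059, 0.0062),
                    musp = c(0.87, 0.67, 0.60),
                    wavelength = c(660, 780, 850))
}

#' Homogeneous phantom scene
#'
#' @param dims scene dimensions (rows, cols), pixels.
#' @param op \linkS4class{OpticalProperties} (one entry per wavelength).
#' @param db Brownian diffusion coefficient, mm^2/s (scalar; default 0).
#' @param name scene identifier.
#' @return a \linkS4class{PhantomScene}.
#' @export
uniformScene <- function(dims, op, db = 0, name = "uniform") {
  dims <- as.integer(dims)
  nw <- length(op@wavelength)
  new("PhantomScene", dims = dims, wavelengths = op@wavelength,
      mua = lapply(seq_len(nw), function(i) matrix(op@mua[i], dims[1], dims[2])),
      musp = lapply(seq_len(nw), function(i) matrix(op@musp[i], dims[1], dims[2])),
      db = matrix(db, dims[1], dims[2]), name = name)
}

#' The four-phantom characterization library
#'
#' Four homogeneous scenes anchored at the calibration-phantom values:
#' phantom 1 is the anchor, phantom 2 doubles mua (same musp), phantom 3
#' doubles musp (same mua), and phantom 4 doubles both. At a fixed Db the
#' forward speckle contrast orders as phantom 2 > phantom 1 > phantom 3,
#' with phantom 4 close to phantom 1 (the joint-scaling invariance of K^2).
#'
#' @param dims scene dimensions (default 64 x 64).
#' @param db common Brownian diffusion coefficient, mm^2/s (default 0).
#' @return named list of four \linkS4class{PhantomScene}s.
#' @export
phantomLibrary <- function(dims = c(64L, 64L), db = 0) {
  base <- calibrationPhantom()
  mk <- function(fa, fs, name) {
    op <- opticalProperties(base@mua * fa, base@musp * fs, base@wavelength)
    uniformScene(dims, op, db = db, name = name)
  }
  list(phantom1 = mk(1, 1, "phantom1"),
       phantom2 = mk(2, 1, "phantom2"),
       phantom3 = mk(1, 2, "phantom3"),
       phantom4 = mk(2, 2, "phantom4"))
}

#' Flow-tube phantom scene
#'
#' Mimics the flow-sensitivity phantom: a static scattering slab with an
#' embedded capillary tube (a vertical band of elevated Db).
#'
#' @param dims scene dimensions, pixels.
#' @param tubeCol centre column of the tube (default image centre).
#' @param tubeRadiusPx tube half-width, pixels (default 1/8 of the width).
#' @param dbTube Db inside the tube, mm^2/s.
#' @param dbBackground Db outside the tube, mm^2/s (default 0).
#' @param op optical properties (default the static flow-phantom values).
#' @return a \linkS4class{PhantomScene}.
#' @export
flowTubeScene <- function(dims, dbTube = 1e-6, dbBackground = 0,
                          tubeCol = ceiling(dims[2] / 2),
                          tubeRadiusPx = max(2L, floor(dims[2] / 8)),
                          op = flowPhantomStatic()) {
  sc <- uniformScene(dims, op, db = dbBackground, name = "flow-tube")
  cols <- abs(seq_len(sc@dims[2]) - tubeCol) <= tubeRadiusPx
  db <- sc@db
  db[, cols] <- dbTube
  sc@db <- db
  sc
}

#' Render the SFDI frames of one acquisition cycle
#'
#' Renders the 18 patterned reflectance frames of a cycle over a phantom
#' scene using the diffuse-reflectance forward model. Each frame is
#' \deqn{I = A_{DC}\,R_d(0) + M_0\,R_d(f_x)\cos(2\pi f_x x + \phi)}
#' pixelwise (for planar fx = 0 slots the modulation term reduces to
#' \eqn{M_0 R_d(0)}, carrying no spatial phase), plus optional additive
#' Gaussian noise. With zero noise the rendering round-trips exactly
#' through demodulation and calibration.
#'
#' @param scene a \linkS4class{PhantomScene} (must include the schedule's
#'   wavelengths).
#' @param schedule a \linkS4class{CycleSchedule}.
#' @param m0 modulation amplitude, counts (default 10000).
#' @param dcAmp planar illumination amplitude, counts (default 60000).
#' @param noiseSd additive Gaussian noise sd, counts (default 0).
#' @param seed RNG seed for the noise (required when noiseSd > 0).
#' @param pixelSizeMm sample-plane pixel pitch, mm (default 10/1200).
#' @param n refractive index for the forward model (default 1.4).
#' @return list of 18 frames (matrices, counts) in slot order, with the
#'   schedule entries attached as attribute \code{"slots"}.
#' @export
renderSfdiFrames <- function(scene, schedule, m0 = 10000, dcAmp = 60000,
                             noiseSd = 0, seed = 1L,
                             pixelSizeMm = 10 / 1200, n = 1.4) {
  stopifnot(is(scene, "PhantomScene"), is(schedule, "CycleSchedule"))
  e <- schedule@entries
  d <- scene@dims
  xMm <- matrix((seq_len(d[2]) - 1) * pixelSizeMm, d[1], d[2], byrow = TRUE)
  render <- function() {
    lapply(seq_len(18L), function(s) {
      wli <- match(e$wavelength[s], scene@wavelengths)
      if (is.na(wli))
        stop("scene lacks properties at ", e$wavelength[s], " nm")
      mua <- scene@mua[[wli]]; musp <- scene@musp[[wli]]
      rd0 <- rdForward(mua, musp, fx = 0, n = n)
      if (e$fx[s] == 0) {
        fr <- dcAmp * rd0 + m0 * rd0
      } else {
        rdf <- rdForward(mua, musp, fx = e$fx[s], n = n)
        fr <- dcAmp * rd0 +
          m0 * rdf * cos(2 * pi * e$fx[s] * xMm + e$phase[s] * pi / 180)
      }
      if (noiseSd > 0) fr <- fr + matrix(stats::rnorm(length(fr), 0, noiseSd),
                                         d[1], d[2])
      pmax(fr, 0)
    })
  }
  frames <- if (noiseSd > 0) .withSeed(seed, render()) else render()
  attr(frames, "slots") <- e
  frames
}

## Discrete exposure-integrated K^2 (beta = 1) for sub-exposure sample
## correlations rho[i, j]: K^2 = mean(rho^2).
.k2Discrete <- function(rho) mean(rho * rho)

#' Decorrelation time reproducing a target Db under the synthesizer
#'
#' The speckle synthesizer uses an exponential field autocorrelation
#' \eqn{g_1(\tau) = e^{-\tau/\tau_c}} sampled at \code{nSub} sub-exposure
#' times. This helper returns the tau_c for which the synthesizer's
#' discrete exposure-integrated contrast equals the correlation-diffusion
#' forward contrast \code{\link{k2Forward}} at the given (db, mua, musp),
#' so closed-loop stacks carry exactly the contrast the Db inversion
#' expects (sub-sampling bias cancels by construction).
#'
#' @inheritParams k2Forward
#' @param nSub number of sub-exposure field samples (must match the
#'   synthesizer call).
#' @return decorrelation time tau_c, seconds.
#' @export
tauCForDb <- function(db, mua, musp, exposure = 0.010, wavelength = 633,
                      n = 1.4, nSub = 32L) {
  stopifnot(db > 0)
  target <- k2Forward(db, mua, musp, beta = 1, exposure = exposure,
                      wavelength = wavelength, n = n)
  ti <- ((seq_len(nSub) - 0.5) / nSub) * exposure
  dt <- abs(outer(ti, ti, "-"))
  f <- function(logTau) .k2Discrete(exp(-dt / exp(logTau))) - target
  r <- stats::uniroot(f, lower = log(exposure * 1e-7),
                      upper = log(exposure * 1e7), tol = 1e-12)
  exp(r$root)
}

## One frame of fully developed speckle: pupil-filtered complex Gaussian
## fields at nSub sub-exposure samples with temporal correlation chol(C),
## intensity averaged over the exposure. mask and cholC are precomputed.
.speckleFrame <- function(d, mask, cholC) {
  nSub <- nrow(cholC)
  npup <- sum(mask)
  W <- matrix(complex(real = stats::rnorm(nSub * npup),
                      imaginary = stats::rnorm(nSub * npup)) / sqrt(2),
              nSub, npup)
  F <- cholC %*% W
  I <- matrix(0, d[1], d[2])
  pupil <- matrix(0 + 0i, d[1], d[2])
  for (i in seq_len(nSub)) {
    pupil[mask] <- F[i, ]
    E <- stats::fft(pupil)
    I <- I + Re(E * Conj(E))
  }
  I / (nSub * npup)
}

#' Simulate a stack of fully developed speckle frames
#'
#' Generates raw LSI frames: each frame is the exposure-integrated
#' intensity of a complex Gaussian speckle field, synthesized by filtering
#' white complex Gaussian noise through a circular pupil (controlling the
#' speckle/pixel size ratio and hence the effective beta) and imposing the
#' field autocorrelation across sub-exposure samples exactly via Cholesky
#' factorisation of the correlation matrix. Frames are statistically
#' independent of one another (only spatial contrast is consumed
#' downstream). A static stack of fully resolved speckle has unit
#' intensity contrast (exponential intensity statistics).
#'
#' @param dims frame dimensions (rows, cols), pixels.
#' @param frames number of frames.
#' @param exposure exposure time T, s (default 0.010).
#' @param tauC field decorrelation time, s; \code{Inf} for a static medium.
#' @param g1 optional function of tau overriding the exponential law.
#' @param nSub sub-exposure field samples per frame (default 32; 1 is exact
#'   for a static medium).
#' @param specklePx approximate speckle diameter, pixels (default 4).
#' @param meanCounts target mean intensity, counts (default 30: fully
#'   developed speckle is exponentially distributed, so the mean is kept at
#'   about 1/8.5 of the 8-bit ceiling to leave the intensity tail
#'   unclipped — saturation preferentially truncates the static
#'   distribution and biases contrast ratios).
#' @param bitDepth quantization depth (default 8); \code{NA} skips
#'   quantization.
#' @param seed RNG seed (mandatory; same seed, same stack).
#' @return array \code{[rows, cols, frames]} of intensity counts.
#' @export
simulateSpeckleStack <- function(dims, frames = 1L, exposure = 0.010,
                                 tauC = Inf, g1 = NULL, nSub = 32L,
                                 specklePx = 4, meanCounts = 30,
                                 bitDepth = 8L, seed) {
  stopifnot(length(dims) == 2L, frames >= 1L, exposure > 0, nSub >= 1L)
  if (missing(seed)) stop("a seed is mandatory")
  d <- as.integer(dims)
  fr <- .fftFreqGrid(d)
  R <- max(1, 0.61 * d[1] / specklePx)
  mask <- fr <= R^2
  static <- is.null(g1) && !is.finite(tauC)
  if (static) nSub <- 1L
  ti <- ((seq_len(nSub) - 0.5) / nSub) * exposure
  dt <- abs(outer(ti, ti, "-"))
  rho <- if (static) matrix(1, 1, 1)
         else if (!is.null(g1)) g1(dt)
         else exp(-dt / tauC)
  ## correlation matrices of smooth g1 laws can be numerically semidefinite
  cholC <- chol(rho + diag(1e-12, nrow(rho)))
  out <- .withSeed(seed, {
    stack <- array(0, c(d[1], d[2], frames))
    for (f in seq_len(frames))
      stack[, , f] <- .speckleFrame(d, mask, t(cholC))
    stack
  })
  out <- out * (meanCounts / mean(out))
  if (!is.na(bitDepth)) {
    out <- round(out)
    out <- pmin(pmax(out, 0), 2^bitDepth - 1)
  }
  out
}

.fftFreqGrid <- function(d) {
  fr <- ((seq_len(d[1]) - 1 + d[1] %/% 2) %% d[1]) - d[1] %/% 2
  fc <- ((seq_len(d[2]) - 1 + d[2] %/% 2) %% d[2]) - d[2] %/% 2
  outer(fr^2, fc^2, "+")
}

#' Simulate the LSI frames of a scene with piecewise-constant dynamics
#'
#' Generates one speckle stack per distinct Db value in the scene (tau_c
#' matched to the correlation-diffusion contrast via
#' \code{\link{tauCForDb}}, using the scene's 633 nm optical properties)
#' and composites them by region mask. Region boundaries are therefore
#' sharp; within-region speckle statistics are exact.
#'
#' @param scene a \linkS4class{PhantomScene} carrying 633 nm properties
#'   (or whose power-law extrapolation is handled upstream); the median
#'   (mua, musp) of each Db region is used for the tau_c match.
#' @param muaLsi,muspLsi matrices of optical properties at the LSI
#'   wavelength for the scene.
#' @param frames number of frames.
#' @inheritParams simulateSpeckleStack
#' @return array \code{[rows, cols, frames]} of 8-bit intensity counts.
#' @export
simulateSceneSpeckle <- function(scene, muaLsi, muspLsi, frames = 18L,
                                 exposure = 0.010, nSub = 32L, specklePx = 4,
                                 meanCounts = 30, seed) {
  stopifnot(is(scene, "PhantomScene"))
  if (missing(seed)) stop("a seed is mandatory")
  d <- scene@dims
  vals <- sort(unique(as.vector(scene@db)))
  stack <- array(0, c(d[1], d[2], frames))
  for (vi in seq_along(vals)) {
    v <- vals[vi]
    m <- scene@db == v
    if (v == 0) {
      sub <- simulateSpeckleStack(d, frames, exposure, tauC = Inf,
                                  nSub = nSub, specklePx = specklePx,
                                  meanCounts = meanCounts, seed = seed + vi)
    } else {
      tc <- tauCForDb(v, stats::median(muaLsi[m]), stats::median(muspLsi[m]),
                      exposure = exposure, nSub = nSub)
      sub <- simulateSpeckleStack(d, frames, exposure, tauC = tc,
                                  nSub = nSub, specklePx = specklePx,
                                  meanCounts = meanCounts, seed = seed + vi)
    }
    for (f in seq_len(frames)) {
      sl <- stack[, , f]
      sl[m] <- sub[, , f][m]
      stack[, , f] <- sl
    }
  }
  stack
}
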