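## SFDI processing: three-phase demodulation -> Gaussian smoothing ->
## phantom calibration -> lookup-table inversion of (mua, musp) ->
## chromophore fitting.

#' Construct a PhaseTriplet
#'
#' @param i1,i2,i3 intensity images at phases 0, 120, 240 degrees (counts).
#' @param fx spatial frequency, mm^-1.
#' @param wavelength wavelength, nm.
#' @return a \linkS4class{PhaseTriplet}.
#' @export
phaseTriplet <- function(i1, i2, i3, fx, wavelength) {
  new("PhaseTriplet", i1 = i1, i2 = i2, i3 = i3, fx = as.numeric(fx),
      wavelength = as.numeric(wavelength))
}

#' Three-phase spatial frequency demodulation
#'
#' For a patterned (fx > 0) triplet the AC amplitude is extracted pixelwise:
#' \deqn{M_{AC} = \frac{\sqrt{2}}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}}
#' \eqn{\sqrt{2}/3} is the unique constant for which a three-phase sinusoid
#' of amplitude A demodulates to exactly A; the formula rejects any common
#' DC offset. A planar (fx = 0) pattern carries no spatial phase — its three
#' frames are nominally identical — so the planar amplitude is the mean of
#' the three frames instead (\code{component = "dc"}).
#'
#' @param t a \linkS4class{PhaseTriplet}.
#' @param component \code{"auto"} (dc if \code{fx == 0}, else ac),
#'   \code{"ac"} or \code{"dc"}.
#' @return a \linkS4class{DemodulatedMap} (unsmoothed).
#' @export
demodulate <- function(t, component = c("auto", "ac", "dc")) {
  stopifnot(is(t, "PhaseTriplet"))
  component <- match.arg(component)
  if (component == "auto") component <- if (t@fx == 0) "dc" else "ac"
  mac <- if (component == "ac") {
    (sqrt(2) / 3) * sqrt((t@i1 - t@i2)^2 + (t@i2 - t@i3)^2 + (t@i3 - t@i1)^2)
  } else {
    (t@i1 + t@i2 + t@i3) / 3
  }
  new("DemodulatedMap", mac = mac, fx = t@fx, wavelength = t@wavelength,
      smoothed = FALSE)
}

## Normalised 1-D Gaussian kernel contained in an odd window.
.gaussKernel <- function(window, sigma) {
  h <- (window - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g / sum(g)
}

## Separable convolution with symmetric (reflective) boundary padding.
.convSeparable <- function(m, kernel) {
  len <- length(kernel)
  if (len == 1L) return(m * kernel)
  h <- (len - 1L) / 2L
  convAlongRows <- function(x) {
    nr <- nrow(x)
    idx <- c(h:1, 1:nr, nr:(nr - h + 1L))
    p <- x[idx, , drop = FALSE]
    out <- matrix(0, nr, ncol(x))
    for (k in seq_len(len))
      out <- out + kernel[k] * p[k:(k + nr - 1L), , drop = FALSE]
    out
  }
  t(convAlongRows(t(convAlongRows(m))))
}

#' Gaussian smoothing of a demodulated amplitude map
#'
#' Separable Gaussian filter applied to the demodulated AC image to suppress
#' shot noise before calibration. Defaults: 15 x 15 pixel window with
#' sigma = window/6 (2.5 px), so the kernel is well contained. The image
#' border is handled with reflective (symmetric) padding; a window of 1 is
#' the identity.
#'
#' @param m a \linkS4class{DemodulatedMap}.
#' @param window odd window size, pixels (default 15).
#' @param sigma Gaussian standard deviation, pixels (default window/6).
#' @return a smoothed \linkS4class{DemodulatedMap}.
#' @export
gaussianSmooth <- function(m, window = 15L, sigma = window / 6) {
  stopifnot(is(m, "DemodulatedMap"), window >= 1, window %% 2 == 1, sigma > 0)
  k <- .gaussKernel(as.integer(window), sigma)
  new("DemodulatedMap", mac = .convSeparable(m@mac, k), fx = m@fx,
      wavelength = m@wavelength, smoothed = TRUE)
}

#' Calibrate a demodulated map against the calibration phantom
#'
#' Converts sample AC amplitude to diffuse reflectance by ratioing against a
#' phantom of known optical properties measured under identical conditions:
#' \deqn{R_d(f_x) = \frac{M_{AC}(f_x)}{M_{AC,phantom}(f_x)} R_{d,phantom}(f_x)}
#' with \eqn{R_{d,phantom}} from the diffusion forward model
#' (\code{\link{rdForward}}).
#'
#' @param m sample \linkS4class{DemodulatedMap}.
#' @param mPhantom phantom \linkS4class{DemodulatedMap}, same fx and
#'   wavelength.
#' @param phantomOp \linkS4class{OpticalProperties} of the phantom (must
#'   include the map's wavelength).
#' @param n refractive index for the forward model (default 1.4).
#' @return an \linkS4class{RdMap}.
#' @export
calibrate <- function(m, mPhantom, phantomOp, n = 1.4) {
  stopifnot(is(m, "DemodulatedMap"), is(mPhantom, "DemodulatedMap"),
            is(phantomOp, "OpticalProperties"))
  if (m@fx != mPhantom@fx || m@wavelength != mPhantom@wavelength)
    stop("sample and phantom maps must share fx and wavelength")
  if (!identical(dim(m@mac), dim(mPhantom@mac)))
    stop("sample and phantom maps must share dimensions")
  nzero <- sum(mPhantom@mac <= 0)
  if (nzero > 0)
    stop(sprintf("phantom amplitude is zero at %d pixel(s); cannot calibrate",
                 nzero))
  i <- match(m@wavelength, phantomOp@wavelength)
  if (is.na(i))
    stop(sprintf("phantom properties do not include %g nm", m@wavelength))
  rdPh <- rdForward(phantomOp@mua[i], phantomOp@musp[i], fx = m@fx, n = n)
  new("RdMap", rd = (m@mac / mPhantom@mac) * rdPh, fx = m@fx,
      wavelength = m@wavelength)
}

#' Build the forward diffuse-reflectance lookup table
#'
#' Evaluates \code{\link{rdForward}} at fx = 0 and the AC frequency over a
#' linearly spaced (mua, musp) grid. Defaults follow the inversion ranges
#' used throughout the package: mua in [0.0001, 0.2] mm^-1 and musp in
#' [0.001, 3] mm^-1, 512 nodes each.
#'
#' @param n refractive index (default 1.4).
#' @param nMua,nMusp number of grid nodes per axis (default 512).
#' @param muaRange,muspRange axis ranges, mm^-1.
#' @param fxAc AC spatial frequency, mm^-1 (default 0.3).
#' @return an \linkS4class{RdLut}.
#' @export
buildRdLut <- function(n = 1.4, nMua = 512L, nMusp = 512L,
                       muaRange = c(1e-4, 0.2), muspRange = c(0.001, 3),
                       fxAc = 0.3) {
  muaAxis <- seq(muaRange[1], muaRange[2], length.out = nMua)
  muspAxis <- seq(muspRange[1], muspRange[2], length.out = nMusp)
  muaG <- matrix(muaAxis, nMua, nMusp)
  muspG <- matrix(muspAxis, nMua, nMusp, byrow = TRUE)
  new("RdLut", muaAxis = muaAxis, muspAxis = muspAxis,
      rd0 = rdForward(muaG, muspG, fx = 0, n = n),
      rd03 = rdForward(muaG, muspG, fx = fxAc, n = n),
      fxAc = fxAc, n = n)
}

#' Invert calibrated reflectance pairs for optical properties
#'
#' Recovers per-pixel (mua, musp) from the pair (Rd(0), Rd(fxAC)) by solving
#' the same closed-form diffusion forward model that generated the lookup
#' table: a damped Newton iteration in (log mua, log musp), seeded at the
#' grid centre. A pixel is flagged invalid when no solution exists (the
#' reflectance pair lies outside the attainable region, e.g. (0.99, 0.99))
#' or when the solution falls outside the table's axis ranges; invalid
#' pixels carry NA rather than extrapolated values, since silent
#' extrapolation produces unphysical mua.
#'
#' @param rd0 \linkS4class{RdMap} at fx = 0.
#' @param rd03 \linkS4class{RdMap} at the AC frequency (same shape and
#'   wavelength).
#' @param lut an \linkS4class{RdLut} defining the admissible ranges, AC
#'   frequency and refractive index.
#' @return an \linkS4class{OpticalPropertyMap}; errors if every pixel is
#'   out of range.
#' @export
invertOpticalProperties <- function(rd0, rd03, lut) {
  stopifnot(is(rd0, "RdMap"), is(rd03, "RdMap"), is(lut, "RdLut"))
  if (!identical(dim(rd0@rd), dim(rd03@rd)))
    stop("rd0 and rd03 must share dimensions")
  if (rd0@wavelength != rd03@wavelength)
    stop("rd0 and rd03 must share wavelength")
  d <- dim(rd0@rd)
  t0 <- as.vector(rd0@rd)
  t3 <- as.vector(rd03@rd)
  sol <- .invertRdPairs(t0, t3, lut)
  muaM <- matrix(sol$mua, d[1], d[2])
  muspM <- matrix(sol$musp, d[1], d[2])
  inv <- matrix(sol$invalid, d[1], d[2])
  if (all(inv)) stop("all pixels are outside the attainable reflectance region")
  new("OpticalPropertyMap", mua = muaM, musp = muspM,
      wavelength = rd0@wavelength, invalid = inv)
}

## Vectorised damped Newton solve of rdForward(mua, musp, {0, fxAc}) =
## (t0, t3) in log space. Duplicate reflectance pairs (homogeneous scenes)
## are solved once.
.invertRdPairs <- function(t0, t3, lut) {
  npx <- length(t0)
  key <- paste(t0, t3)
  first <- !duplicated(key)
  map <- match(key, key[first])
  q0 <- t0[first]; q3 <- t3[first]
  nq <- length(q0)
  n <- lut@n; fxAc <- lut@fxAc
  u <- rep(log(0.02), nq)    # log mua
  v <- rep(log(1.0), nq)     # log musp
  bad <- !is.finite(q0) | !is.finite(q3) | q0 <= 0 | q3 <= 0
  resid <- function(u, v) {
    mua <- exp(u); musp <- exp(v)
    cbind(rdForward(mua, musp, fx = 0, n = n) - q0,
          rdForward(mua, musp, fx = fxAc, n = n) - q3)
  }
  r <- resid(u, v)
  rn <- sqrt(rowSums(r^2))
  h <- 1e-6
  for (iter in seq_len(80)) {
    active <- !bad & rn > 1e-13
    if (!any(active)) break
    r0u <- resid(u + h, v) - resid(u - h, v)
    r0v <- resid(u, v + h) - resid(u, v - h)
    j11 <- r0u[, 1] / (2 * h); j21 <- r0u[, 2] / (2 * h)
    j12 <- r0v[, 1] / (2 * h); j22 <- r0v[, 2] / (2 * h)
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- NA
    du <- -(j22 * r[, 1] - j12 * r[, 2]) / det
    dv <- -(-j21 * r[, 1] + j11 * r[, 2]) / det
    du[!active | is.na(du)] <- 0
    dv[!active | is.na(dv)] <- 0
    du <- pmax(pmin(du, 1.5), -1.5)
    dv <- pmax(pmin(dv, 1.5), -1.5)
    step <- rep(1, nq)
    for (bt in seq_len(6)) {
      un <- u + step * du
      vn <- v + step * dv
      rNew <- resid(un, vn)
      rnNew <- sqrt(rowSums(rNew^2))
      worse <- active & !is.na(rnNew) & rnNew > rn
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    u <- u + step * du
    v <- v + step * dv
    r <- resid(u, v)
    rn <- sqrt(rowSums(r^2))
    rn[is.na(rn)] <- Inf
  }
  mua <- exp(u); musp <- exp(v)
  tol <- 1e-9
  inRange <- mua >= min(lut@muaAxis) - 1e-12 & mua <= max(lut@muaAxis) + 1e-12 &
    musp >= min(lut@muspAxis) - 1e-12 & musp <= max(lut@muspAxis) + 1e-12
  invalid <- bad | rn > tol | !inRange
  mua[invalid] <- NA_real_
  musp[invalid] <- NA_real_
  list(mua = mua[map], musp = musp[map], invalid = invalid[map])
}

#' Fit hemoglobin chromophores from multi-wavelength absorption maps
#'
#' Per-pixel least-squares solve of the extinction system
#' \eqn{E c = \mu_a} for \eqn{c = (C_{HbO2}, C_{HbR})} (uM), where E is the
#' extinction matrix in mm^-1/uM (including the ln 10 factor; see
#' \code{\link{extinctionMatrix}}). Total hemoglobin and oxygen saturation
#' follow as \eqn{HbT = C_{HbO2} + C_{HbR}} and
#' \eqn{StO_2 = 100\, C_{HbO2}/HbT}.
#'
#' @param muaMaps list of absorption maps (matrices, mm^-1), one per
#'   wavelength; NA pixels propagate.
#' @param eps extinction matrix, \code{length(muaMaps)} rows and columns
#'   (HbO2, HbR); must have full column rank.
#' @return a \linkS4class{ChromophoreMap}.
#' @export
fitChromophores <- function(muaMaps, eps) {
  stopifnot(is.list(muaMaps), length(muaMaps) >= 2L, is.matrix(eps),
            nrow(eps) == length(muaMaps), ncol(eps) == 2L)
  if (qr(eps)$rank < 2L) stop("extinction matrix is rank deficient")
  d <- dim(muaMaps[[1]])
  for (m in muaMaps) stopifnot(identical(dim(m), d))
  M <- do.call(rbind, lapply(muaMaps, as.vector))  # nWl x npix
  ## normal equations of the per-pixel least-squares problem
  C <- solve(crossprod(eps), crossprod(eps, M))    # 2 x npix
  cHbO2 <- matrix(C[1, ], d[1], d[2])
  cHbR <- matrix(C[2, ], d[1], d[2])
  hbt <- cHbO2 + cHbR
  sto2 <- ifelse(!is.na(hbt) & hbt > 0, 100 * cHbO2 / hbt, NA_real_)
  new("ChromophoreMap", cHbO2 = cHbO2, cHbR = cHbR, hbt = hbt,
      sto2 = matrix(sto2, d[1], d[2]))
}
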