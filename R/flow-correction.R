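## Correction of speckle contrast for tissue optical properties: the
## exposure-integrated K^2 forward model from the correlation diffusion
## equation, a 3-D lookup table over (Db, mua, musp), and its monotone
## inversion for the absolute Brownian diffusion coefficient Db.

#' Forward speckle contrast from the correlation diffusion equation
#'
#' Exposure-integrated squared speckle contrast for a homogeneous
#' semi-infinite medium with Brownian scatterer dynamics:
#' \deqn{K^2 = \frac{2\beta}{T}\int_0^T g_1^2(\tau)\Big(1-\frac{\tau}{T}\Big)d\tau}
#' with the normalized field autocorrelation \eqn{g_1} of
#' \code{\link{g1Normalized}} (fx = 0: LSI illumination is planar). The
#' integral is evaluated by adaptive Gauss-Kronrod quadrature with relative
#' tolerance 1e-9. In the static limit (db = 0) the integrand reduces to
#' \eqn{(1-\tau/T)} and \eqn{K^2 = \beta} exactly. At fx = 0, jointly
#' scaling mua and musp by a common factor leaves \eqn{K^2} unchanged.
#'
#' @param db Brownian diffusion coefficient, mm^2/s (scalar or vector).
#' @param mua,musp optical properties at the LSI wavelength, mm^-1.
#' @param beta speckle normalization factor (\linkS4class{BetaFactor} or a
#'   number in (0, 1]; default 1).
#' @param exposure exposure time T, s (default 0.010).
#' @param wavelength LSI wavelength, nm (default 633).
#' @param n refractive index (default 1.4).
#' @param fx spatial frequency, mm^-1 (default 0; retained for testing).
#' @return K^2 value(s) in (0, beta].
#' @examples
#' sqrt(k2Forward(0, 0.02, 1.0))        # static limit: K = 1
#' k2Forward(1e-6, 0.02, 1.0)           # dynamic medium
#' @export
k2Forward <- function(db, mua, musp, beta = 1, exposure = 0.010,
                      wavelength = 633, n = 1.4, fx = 0) {
  if (is(beta, "BetaFactor")) beta <- beta@beta
  stopifnot(all(db >= 0), all(mua > 0), all(musp > 0), exposure > 0,
            beta > 0, beta <= 1)
  if (length(db) > 1L || length(mua) > 1L || length(musp) > 1L) {
    m <- cbind(db = db, mua = mua, musp = musp)  # recycles
    return(vapply(seq_len(nrow(m)), function(i)
      k2Forward(m[i, 1], m[i, 2], m[i, 3], beta, exposure, wavelength, n, fx),
      numeric(1)))
  }
  a <- boundaryTerms(n)@a
  Tt <- exposure
  f <- function(tau)
    .g1n(tau, mua, musp, db, wavelength, n, fx, a)^2 * (1 - tau / Tt)
  q <- tryCatch(
    stats::integrate(f, 0, Tt, rel.tol = 1e-9, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) stop("K^2 quadrature failed (db = ", db,
                             ", mua = ", mua, ", musp = ", musp, "): ",
                             conditionMessage(e)))
  (2 * beta / Tt) * q$value
}

#' Build the K^2 lookup table over (Db, mua, musp)
#'
#' Tabulates the \code{\link{k2Forward}} model on a 3-D grid for fast
#' inversion of measured contrast. Default axes: Db linear from 0 to
#' 2e-5 mm^2/s with 256 nodes; mua in [0.0001, 0.3] and musp in [0.001, 3]
#' mm^-1 with 128 nodes each. The db = 0 slice is the exact static limit
#' (K^2 = beta); the remaining slices are integrated with a fixed
#' Gauss-Legendre rule on a log-stretched time axis, vectorised across the
#' optical-property grid, which agrees with the adaptive quadrature of
#' \code{\link{k2Forward}} to well below 1e-8 relative.
#'
#' @inheritParams k2Forward
#' @param dbMax upper Db bound, mm^2/s (default 2e-5).
#' @param nDb,nMua,nMusp axis node counts.
#' @param muaRange,muspRange optical property axis ranges, mm^-1.
#' @param quadNodes Gauss-Legendre node count (default 256).
#' @return a \linkS4class{K2Lut}.
#' @export
buildK2Lut <- function(beta = 1, exposure = 0.010, wavelength = 633, n = 1.4,
                       dbMax = 20e-6, nDb = 256L, nMua = 128L, nMusp = 128L,
                       muaRange = c(1e-4, 0.3), muspRange = c(0.001, 3),
                       quadNodes = 256L) {
  if (is(beta, "BetaFactor")) beta <- beta@beta
  stopifnot(beta > 0, beta <= 1, exposure > 0, dbMax > 0)
  dbAxis <- seq(0, dbMax, length.out = nDb)
  muaAxis <- seq(muaRange[1], muaRange[2], length.out = nMua)
  muspAxis <- seq(muspRange[1], muspRange[2], length.out = nMusp)
  a <- boundaryTerms(n)@a
  Tt <- exposure
  muaG <- matrix(muaAxis, nMua, nMusp)
  muspG <- matrix(muspAxis, nMua, nMusp, byrow = TRUE)
  mutr <- muaG + muspG
  k0 <- .k0(wavelength, n)
  E0 <- 3 * muaG * mutr                 # static mueff^2
  Cg <- 6 * k0^2 * muspG * mutr         # dynamic mueff^2 per (db*tau)
  x0 <- sqrt(E0) / mutr
  N0 <- (x0 + 1) * (x0 + 3 * a)
  ## tau = T * exp(-L (1 - u)), u in (0, 1): log-stretched axis resolving
  ## decay scales down to T e^-L while integrating the slow limit exactly.
  L <- 34
  gl <- pracma::gaussLegendre(as.integer(quadNodes), 0, 1)
  tauq <- Tt * exp(-L * (1 - gl$x))
  wq <- gl$w * L * tauq * (1 - tauq / Tt)   # includes d tau/du and (1-tau/T)
  k2 <- array(NA_real_, c(nDb, nMua, nMusp))
  k2[1, , ] <- beta                          # exact static limit
  for (i in seq_len(nDb)[-1]) {
    acc <- matrix(0, nMua, nMusp)
    dbi <- dbAxis[i]
    for (q in seq_along(tauq)) {
      x <- sqrt(E0 + Cg * (dbi * tauq[q])) / mutr
      g1 <- N0 / ((x + 1) * (x + 3 * a))
      acc <- acc + wq[q] * g1 * g1
    }
    k2[i, , ] <- (2 * beta / Tt) * acc
  }
  new("K2Lut", dbAxis = dbAxis, muaAxis = muaAxis, muspAxis = muspAxis,
      k2 = k2, beta = beta, exposure = exposure, wavelength = wavelength,
      n = n)
}

## Bilinear interpolation weights along an axis; errors outside the axis.
.axisWeights <- function(axis, x, what) {
  if (any(x < axis[1] - 1e-12 | x > axis[length(axis)] + 1e-12, na.rm = TRUE))
    stop(what, " outside the lookup-table axis range [",
         axis[1], ", ", axis[length(axis)], "]")
  x <- pmin(pmax(x, axis[1]), axis[length(axis)])
  i <- findInterval(x, axis, rightmost.closed = TRUE)
  i <- pmin(i, length(axis) - 1L)
  t <- (x - axis[i]) / (axis[i + 1L] - axis[i])
  list(i = i, t = t)
}

#' Invert measured speckle contrast for the Brownian diffusion coefficient
#'
#' Given measured contrast K and optical properties at the LSI wavelength,
#' recovers Db such that the forward model reproduces K^2: the (mua, musp)
#' coordinates are fixed by bilinear interpolation of the lookup table, and
#' the resulting strictly decreasing K^2(Db) profile is inverted by 1-D
#' monotone interpolation along the Db axis. Pixels with K^2 > beta
#' (super-static, unphysical) or K^2 below the profile minimum (flow beyond
#' the table's dynamic range) are flagged invalid (NA). Optical properties
#' outside the table axes raise an error.
#'
#' @param k measured speckle contrast (scalar, vector or matrix).
#' @param mua,musp optical properties at the LSI wavelength, mm^-1 (same
#'   shape as \code{k}, or scalars).
#' @param lut a \linkS4class{K2Lut}.
#' @return Db values, mm^2/s, with NA where invalid; same shape as \code{k}.
#' @export
invertDb <- function(k, mua, musp, lut) {
  stopifnot(is(lut, "K2Lut"))
  shape <- dim(k)
  k <- as.vector(k); mua <- as.vector(mua); musp <- as.vector(musp)
  npx <- max(length(k), length(mua), length(musp))
  k <- rep_len(k, npx); mua <- rep_len(mua, npx); musp <- rep_len(musp, npx)
  db <- rep(NA_real_, npx)
  use <- !is.na(k) & !is.na(mua) & !is.na(musp)
  if (any(use)) {
    wa <- .axisWeights(lut@muaAxis, mua[use], "mua")
    ws <- .axisWeights(lut@muspAxis, musp[use], "musp")
    k2t <- k[use]^2
    nDb <- length(lut@dbAxis)
    km <- matrix(lut@k2, nDb)  # nDb x (nMua*nMusp)
    nMua <- length(lut@muaAxis)
    id11 <- (ws$i - 1L) * nMua + wa$i
    id21 <- id11 + 1L
    id12 <- ws$i * nMua + wa$i
    id22 <- id12 + 1L
    res <- rep(NA_real_, length(k2t))
    chunk <- 4096L
    starts <- seq(1L, length(k2t), by = chunk)
    for (s in starts) {
      e <- min(s + chunk - 1L, length(k2t))
      sel <- s:e
      ta <- wa$t[sel]; ts <- ws$t[sel]
      P <- km[, id11[sel], drop = FALSE] *
        rep((1 - ta) * (1 - ts), each = nDb) +
        km[, id21[sel], drop = FALSE] * rep(ta * (1 - ts), each = nDb) +
        km[, id12[sel], drop = FALSE] * rep((1 - ta) * ts, each = nDb) +
        km[, id22[sel], drop = FALSE] * rep(ta * ts, each = nDb)
      tv <- k2t[sel]
      cnt <- colSums(P >= rep(tv, each = nDb))
      out <- rep(NA_real_, length(sel))
      super <- tv > P[1, ] * (1 + 1e-12)        # K^2 > beta
      atMax <- !super & cnt == 0L               # numerically at the static limit
      out[atMax] <- 0
      beyond <- cnt == nDb & tv < P[nDb, ] * (1 - 1e-12)
      out[cnt == nDb & !beyond] <- lut@dbAxis[nDb]
      mid <- !super & !beyond & cnt >= 1L & cnt < nDb
      if (any(mid)) {
        i0 <- cnt[mid]
        p0 <- P[cbind(i0, which(mid))]
        p1 <- P[cbind(i0 + 1L, which(mid))]
        f <- (p0 - tv[mid]) / (p0 - p1)
        out[mid] <- lut@dbAxis[i0] + f * (lut@dbAxis[i0 + 1L] - lut@dbAxis[i0])
      }
      res[sel] <- out
    }
    db[use] <- res
  }
  if (!is.null(shape)) dim(db) <- shape
  db
}

#' Db map from a contrast map and optical property maps
#'
#' Convenience wrapper applying \code{\link{invertDb}} pixelwise and
#' packaging the result (with the union of input invalid masks and
#' out-of-range flags) as a \linkS4class{FlowMap}.
#'
#' @param contrast a \linkS4class{ContrastMap} at the LSI wavelength.
#' @param muaMap,muspMap matrices of optical properties at the LSI
#'   wavelength, mm^-1.
#' @param lut a \linkS4class{K2Lut} built with the same exposure and beta as
#'   the measurement.
#' @return a \linkS4class{FlowMap} with \code{kind = "db"}.
#' @export
dbMap <- function(contrast, muaMap, muspMap, lut) {
  stopifnot(is(contrast, "ContrastMap"))
  if (abs(contrast@exposure - lut@exposure) > 1e-12)
    stop("contrast map exposure does not match the lookup table")
  v <- invertDb(contrast@k, muaMap, muspMap, lut)
  invalid <- is.na(v)
  new("FlowMap", values = v, kind = "db", invalid = invalid)
}

#' Fit the reduced-scattering power law
#'
#' Fits \eqn{\mu_s'(\lambda) = A\,(\lambda/850)^b} by least squares in log
#' space: \eqn{\log \mu_s' = \log A + b \log(\lambda/850)}. Exact when the
#' inputs lie on a power law; with equal musp at all wavelengths, b = 0 and
#' A equals that value.
#'
#' @param muspValues reduced scattering coefficients, mm^-1 (> 0).
#' @param wavelengths matching wavelengths, nm (>= 2).
#' @param refWavelength reference wavelength, nm (default 850).
#' @return a \linkS4class{PowerLawFit}.
#' @examples
#' fitMusPowerlaw(c(1.07, 0.83, 0.72), c(660, 780, 850))
#' @export
fitMusPowerlaw <- function(muspValues, wavelengths, refWavelength = 850) {
  stopifnot(length(muspValues) == length(wavelengths),
            length(muspValues) >= 2L)
  if (any(!is.finite(muspValues)) || any(muspValues <= 0))
    stop("musp values must be finite and > 0")
  X <- cbind(1, log(wavelengths / refWavelength))
  cf <- qr.solve(X, log(muspValues))
  new("PowerLawFit", amp = exp(cf[1]), slope = cf[2],
      refWavelength = refWavelength)
}

#' Evaluate a scattering power-law fit at a wavelength
#'
#' Forward solution \eqn{\mu_s'(\lambda) = A\,(\lambda/\lambda_{ref})^b},
#' used to transfer SFDI scattering measurements to the LSI wavelength.
#'
#' @param fit a \linkS4class{PowerLawFit}.
#' @param wavelength target wavelength, nm (> 0).
#' @return musp at the target wavelength, mm^-1.
#' @export
extrapolateMusp <- function(fit, wavelength) {
  stopifnot(is(fit, "PowerLawFit"), all(wavelength > 0))
  fit@amp * (wavelength / fit@refWavelength)^fit@slope
}

## Per-pixel power-law fit across wavelength-stacked musp maps; closed-form
## least squares with a shared design matrix.
.fitMusPowerlawMap <- function(muspMaps, wavelengths, refWavelength = 850) {
  d <- dim(muspMaps[[1]])
  M <- do.call(rbind, lapply(muspMaps, function(m) log(as.vector(m))))
  X <- cbind(1, log(wavelengths / refWavelength))
  B <- solve(crossprod(X), crossprod(X, M))   # 2 x npix
  list(amp = matrix(exp(B[1, ]), d[1], d[2]),
       slope = matrix(B[2, ], d[1], d[2]))
}

#' Percent-difference map between normalized Db and SFI images
#'
#' Each map is first normalized to its centre pixel, then
#' \deqn{\%\,Difference = (D_{b,norm} - SFI_{norm}) / SFI_{norm} \times 100.}
#' Maps that are proportional to one another give 0 everywhere. The formula
#' is asymmetric in its arguments.
#'
#' @param dbMap,sfiMap matrices (or \linkS4class{FlowMap}s) of matching
#'   shape; the centre pixels must be nonzero.
#' @return percent-difference matrix.
#' @export
percentDifferenceMap <- function(dbMap, sfiMap) {
  if (is(dbMap, "FlowMap")) dbMap <- mapValues(dbMap)
  if (is(sfiMap, "FlowMap")) sfiMap <- mapValues(sfiMap)
  stopifnot(identical(dim(dbMap), dim(sfiMap)))
  ctr <- function(m) m[ceiling(nrow(m) / 2), ceiling(ncol(m) / 2)]
  c1 <- ctr(dbMap); c2 <- ctr(sfiMap)
  if (is.na(c1) || is.na(c2) || c1 == 0 || c2 == 0)
    stop("centre pixel is zero or NA; cannot normalize")
  dbn <- dbMap / c1
  sfin <- sfiMap / c2
  (dbn - sfin) / sfin * 100
}

#' Save / load a K^2 lookup table
#'
#' Serializes a \linkS4class{K2Lut} (axes, grid and build parameters) to a
#' portable RDS container tagged with a content hash of its parameters.
#'
#' @param lut a \linkS4class{K2Lut}.
#' @param path file path.
#' @return \code{saveK2Lut} returns the path invisibly; \code{loadK2Lut}
#'   returns the \linkS4class{K2Lut}.
#' @export
saveK2Lut <- function(lut, path) {
  stopifnot(is(lut, "K2Lut"))
  saveRDS(list(version = 1L, lut = lut), path)
  invisible(path)
}

#' @rdname saveK2Lut
#' @export
loadK2Lut <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), is(obj$lut, "K2Lut"))
  obj$lut
}
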