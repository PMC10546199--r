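## Shared test helpers: independent brute-force oracles and small fixture
## builders. Oracles are deliberately written against the formulas directly,
## not against package internals.

## Brute-force sliding-window contrast at pixel (i, j): sample sd / mean of
## the raw window values.
bruteWindowContrast <- function(frame, i, j, window = 5L) {
  h <- (window - 1L) / 2L
  v <- as.vector(frame[(i - h):(i + h), (j - h):(j + h)])
  stats::sd(v) / mean(v)
}

## Independent evaluation of the normalized correlation-diffusion field
## autocorrelation (boundary polynomial, transport terms and all), kept
## separate from the package implementation.
oracleG1 <- function(tau, mua, musp, db, lambda = 633, n = 1.4, fx = 0) {
  reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - reff) / (2 * (1 + reff))
  mutr <- mua + musp
  k0 <- 2 * pi * n / (lambda * 1e-6)
  me <- function(t)
    sqrt(3 * (mua + (1 / 3) * musp * k0^2 * 6 * db * t) * mutr + (2 * pi * fx)^2)
  x0 <- me(0) / mutr
  xt <- me(tau) / mutr
  ((x0 + 1) * (x0 + 3 * A)) / ((xt + 1) * (xt + 3 * A))
}

## Brute-force exposure integral of the K^2 model: composite Simpson rule on
## a fixed uniform grid of 1e5 intervals.
oracleK2 <- function(db, mua, musp, beta = 1, exposure = 0.01,
                     lambda = 633, n = 1.4, nIntervals = 1e5) {
  tau <- seq(0, exposure, length.out = nIntervals + 1)
  f <- oracleG1(tau, mua, musp, db, lambda, n)^2 * (1 - tau / exposure)
  h <- exposure / nIntervals
  w <- rep(c(4, 2), length.out = nIntervals - 1)
  integral <- h / 3 * (f[1] + f[nIntervals + 1] + sum(w * f[2:nIntervals]))
  (2 * beta / exposure) * integral
}

## A homogeneous RdMap pair rendered directly from the forward model.
rdMapPair <- function(mua, musp, dims = c(4L, 4L), wavelength = 660,
                      n = 1.4, fxAc = 0.3) {
  list(rd0 = new("RdMap", rd = matrix(rdForward(mua, musp, 0, n),
                                      dims[1], dims[2]),
                 fx = 0, wavelength = wavelength),
       rd3 = new("RdMap", rd = matrix(rdForward(mua, musp, fxAc, n),
                                      dims[1], dims[2]),
                 fx = fxAc, wavelength = wavelength))
}

## Minimal ContrastMap around a constant K value.
constantContrast <- function(k, dims = c(8L, 8L), exposure = 0.01,
                             window = 5) {
  new("ContrastMap", k = matrix(k, dims[1], dims[2]), exposure = exposure,
      window = window, invalid = matrix(FALSE, dims[1], dims[2]))
}
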