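test_that("static limit of the contrast model is exact", {
  expect_equal(k2Forward(0, 0.02, 1.0, beta = 1), 1, tolerance = 1e-12)
  set.seed(11)
  for (i in seq_len(20)) {
    mua <- runif(1, 0.005, 0.2)
    musp <- runif(1, 0.3, 2.8)
    beta <- runif(1, 0.2, 1)
    Texp <- runif(1, 0.002, 0.02)
    k <- sqrt(k2Forward(0, mua, musp, beta = beta, exposure = Texp))
    expect_equal(k, sqrt(beta), tolerance = 1e-9)
  }
})

test_that("K^2 is invariant to joint scaling of mua and musp at fx = 0", {
  base <- k2Forward(1e-6, 0.02, 1.0)
  for (c in c(0.5, 1.5, 3)) {
    expect_lt(abs(k2Forward(1e-6, 0.02 * c, 1.0 * c) - base) / base, 1e-9)
  }
})

test_that("beta enters the contrast model as a pure prefactor", {
  full <- k2Forward(5e-7, 0.03, 1.2, beta = 1)
  half <- k2Forward(5e-7, 0.03, 1.2, beta = 0.5)
  expect_equal(half, 0.5 * full, tolerance = 1e-12)
})

test_that("adaptive quadrature agrees with a brute-force fixed-grid oracle", {
  set.seed(12)
  for (i in seq_len(20)) {
    db <- 10^runif(1, -8, -6)
    mua <- runif(1, 0.01, 0.15)
    musp <- runif(1, 0.5, 2.5)
    ours <- k2Forward(db, mua, musp)
    ref <- oracleK2(db, mua, musp)
    expect_lt(abs(ours - ref) / ref, 1e-8)
  }
})

test_that("K^2 is monotone in db, mua and musp as the phantom ordering predicts", {
  dbs <- c(1e-7, 5e-7, 1e-6, 5e-6, 1e-5)
  k2db <- k2Forward(dbs, 0.02, 1.0)
  expect_true(all(diff(k2db) < 0))
  muas <- c(0.005, 0.02, 0.08, 0.15)
  k2mua <- k2Forward(1e-6, muas, 1.0)
  expect_true(all(diff(k2mua) > 0))
  musps <- c(0.5, 1.0, 2.0, 2.8)
  k2musp <- k2Forward(1e-6, 0.02, musps)
  expect_true(all(diff(k2musp) < 0))
  ## four-phantom ordering at fixed db: doubling mua raises K, doubling
  ## musp lowers it, doubling both restores it
  k1 <- k2Forward(1e-6, 0.019, 1.07)
  k2 <- k2Forward(1e-6, 2 * 0.019, 1.07)
  k3 <- k2Forward(1e-6, 0.019, 2 * 1.07)
  k4 <- k2Forward(1e-6, 2 * 0.019, 2 * 1.07)
  expect_gt(k2, k1)
  expect_lt(k3, k1)
  expect_lt(abs(k4 - k1) / k1, 1e-9)
})

test_that("K^2 lookup table is exact at the static slice and decreasing in db", {
  lut <- buildK2Lut(beta = 0.8, nDb = 48L, nMua = 12L, nMusp = 12L)
  expect_identical(dim(lut@k2), c(48L, 12L, 12L))
  expect_true(all(lut@k2[1, , ] == 0.8))
  ## every db column strictly decreasing
  expect_true(all(apply(lut@k2, c(2, 3), function(col) all(diff(col) < 0))))
  ## table nodes agree with the adaptive quadrature route
  set.seed(13)
  for (r in seq_len(10)) {
    i <- sample(2:48, 1); j <- sample(12, 1); l <- sample(12, 1)
    ref <- k2Forward(lut@dbAxis[i], lut@muaAxis[j], lut@muspAxis[l],
                     beta = 0.8)
    expect_lt(abs(lut@k2[i, j, l] - ref) / ref, 1e-8)
  }
  ## printed default axes
  f <- formals(buildK2Lut)
  expect_identical(eval(f$nDb), 256L)
  expect_identical(eval(f$nMua), 128L)
  expect_identical(eval(f$nMusp), 128L)
  expect_equal(eval(f$dbMax), 20e-6)
})

test_that("Db inversion round-trips forward contrast within 2%", {
  lut <- buildK2Lut(beta = 1, nDb = 128L, nMua = 48L, nMusp = 48L)
  set.seed(14)
  for (i in seq_len(50)) {
    db <- runif(1, 1e-6, 1.8e-5)
    mua <- runif(1, 0.005, 0.25)
    musp <- runif(1, 0.3, 2.5)
    k <- sqrt(k2Forward(db, mua, musp))
    rec <- invertDb(k, mua, musp, lut)
    expect_lt(abs(rec - db) / db, 0.02)
  }
  ## static contrast maps to db = 0, super-static contrast is invalid
  expect_equal(invertDb(1, 0.02, 1.0, lut), 0)
  expect_true(is.na(invertDb(1.05, 0.02, 1.0, lut)))
  expect_error(invertDb(0.3, 0.5, 1.0, lut), "outside")
})

test_that("Db maps propagate invalid pixels and check exposure", {
  lut <- buildK2Lut(beta = 0.64, nDb = 64L, nMua = 16L, nMusp = 16L)
  k <- matrix(sqrt(0.64 * k2Forward(1e-6, 0.02, 1.0)), 4, 4)
  k[1, 1] <- NA
  cm <- new("ContrastMap", k = k, exposure = 0.01, window = 5,
            invalid = is.na(k))
  fm <- dbMap(cm, matrix(0.02, 4, 4), matrix(1.0, 4, 4), lut)
  expect_s4_class(fm, "FlowMap")
  expect_true(invalidMask(fm)[1, 1])
  expect_equal(mapValues(fm)[2, 2], 1e-6, tolerance = 0.02)
  cm@exposure <- 0.02
  expect_error(dbMap(cm, matrix(0.02, 4, 4), matrix(1.0, 4, 4), lut),
               "exposure")
})

test_that("scattering power-law fit matches an independent regression", {
  ## synthetic power law recovered exactly
  fit <- fitMusPowerlaw(1.2 * (c(660, 780, 850) / 850)^(-1.3),
                        c(660, 780, 850))
  expect_equal(fit@amp, 1.2, tolerance = 1e-10)
  expect_equal(fit@slope, -1.3, tolerance = 1e-10)
  ## flat spectrum
  flat <- fitMusPowerlaw(c(0.9, 0.9, 0.9), c(660, 780, 850))
  expect_equal(flat@slope, 0, tolerance = 1e-12)
  expect_equal(flat@amp, 0.9, tolerance = 1e-12)
  ## calibration-phantom values: frozen from an independent log-space fit
  fit <- fitMusPowerlaw(c(1.07, 0.83, 0.72), c(660, 780, 850))
  expect_equal(fit@amp, 0.7223323795, tolerance = 1e-9)
  expect_equal(fit@slope, -1.5596751923, tolerance = 1e-8)
  expect_equal(extrapolateMusp(fit, 633), 1.1439294458, tolerance = 1e-8)
  ## reference wavelength returns the amplitude
  expect_equal(extrapolateMusp(fit, 850), fit@amp)
  z <- new("PowerLawFit", amp = 1.4, slope = 0, refWavelength = 850)
  expect_equal(extrapolateMusp(z, 500), 1.4)
  expect_error(fitMusPowerlaw(c(1, -1, 1), c(660, 780, 850)), "> 0")
})

test_that("absorption transfers to the LSI wavelength through the chromophores", {
  E <- extinctionMatrix(c(660, 780, 850))
  cHbO2 <- matrix(c(40, 80), 1, 2)
  cHbR <- matrix(c(30, 20), 1, 2)
  muaMaps <- lapply(seq_len(3), function(i) E[i, 1] * cHbO2 + E[i, 2] * cHbR)
  ch <- fitChromophores(muaMaps, E)
  mua633 <- muaAtWavelength(ch, 633)
  E633 <- extinctionMatrix(633)
  expect_equal(mua633, E633[1, 1] * cHbO2 + E633[1, 2] * cHbR,
               tolerance = 1e-10)
  ## zero concentrations and linear doubling
  zero <- fitChromophores(list(matrix(0, 2, 2), matrix(0, 2, 2),
                               matrix(0, 2, 2)), E)
  expect_equal(muaAtWavelength(zero), matrix(0, 2, 2))
  ch2 <- fitChromophores(lapply(muaMaps, `*`, 2), E)
  expect_equal(muaAtWavelength(ch2), 2 * mua633, tolerance = 1e-10)
})

test_that("percent-difference maps normalize to the centre pixel", {
  a <- matrix(runif(25, 1, 2), 5, 5)
  ## proportional maps give zero everywhere
  expect_lt(max(abs(percentDifferenceMap(3 * a, a))), 1e-10)
  ## +10% at a pixel
  dbn <- matrix(1, 3, 3); sfin <- matrix(1, 3, 3)
  dbn[1, 1] <- 1.1
  expect_equal(percentDifferenceMap(dbn, sfin)[1, 1], 10, tolerance = 1e-10)
  ## the formula is asymmetric in its arguments
  set.seed(15)
  x <- matrix(runif(25, 0.5, 2), 5, 5); y <- matrix(runif(25, 0.5, 2), 5, 5)
  expect_gt(max(abs(percentDifferenceMap(x, y) +
                    percentDifferenceMap(y, x))), 1e-6)
  bad <- a; bad[3, 3] <- 0
  expect_error(percentDifferenceMap(a, bad), "centre")
})

test_that("K^2 lookup tables serialize and reload", {
  lut <- buildK2Lut(beta = 0.5, nDb = 16L, nMua = 8L, nMusp = 8L)
  p <- tempfile(fileext = ".rds")
  saveK2Lut(lut, p)
  back <- loadK2Lut(p)
  expect_equal(back@k2, lut@k2)
  expect_equal(back@beta, 0.5)
  unlink(p)
})
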