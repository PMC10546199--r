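test_that("three-phase demodulation recovers sinusoid amplitude and rejects DC", {
  d <- c(32L, 48L)
  x <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  mk <- function(phi) 10 + 5 * cos(2 * pi * 0.02 * x + phi)
  tr <- phaseTriplet(mk(0), mk(2 * pi / 3), mk(4 * pi / 3), fx = 0.1,
                     wavelength = 660)
  m <- demodulate(tr)
  expect_equal(max(abs(m@mac - 5)), 0, tolerance = 1e-10)
  ## constant triplet demodulates to zero
  k <- matrix(7, 4, 4)
  z <- demodulate(phaseTriplet(k, k, k, 0.1, 660))
  expect_true(all(z@mac == 0))
  ## hand-evaluated single pixel
  p <- demodulate(phaseTriplet(matrix(1), matrix(0), matrix(0), 0.1, 660))
  expect_equal(p@mac[1, 1], 2 / 3, tolerance = 1e-12)
  ## DC rejection: common offsets cancel exactly
  tr2 <- phaseTriplet(mk(0) + 123, mk(2 * pi / 3) + 123, mk(4 * pi / 3) + 123,
                      fx = 0.1, wavelength = 660)
  expect_lt(max(abs(demodulate(tr2)@mac - m@mac)), 1e-9)
  ## planar slots use the phase mean
  dc <- demodulate(phaseTriplet(k, k, k, 0, 660))
  expect_true(all(dc@mac == 7))
  expect_error(demodulate(phaseTriplet(k, k, matrix(1, 2, 2), 0.1, 660)))
})

test_that("gaussian smoothing preserves constants and normalization", {
  m <- new("DemodulatedMap", mac = matrix(3.5, 20, 20), fx = 0.3,
           wavelength = 660, smoothed = FALSE)
  s <- gaussianSmooth(m)
  expect_equal(max(abs(s@mac - 3.5)), 0, tolerance = 1e-12)
  expect_true(s@smoothed)
  ## unit impulse maps to the kernel, summing to 1
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  mi <- new("DemodulatedMap", mac = imp, fx = 0.3, wavelength = 660,
            smoothed = FALSE)
  si <- gaussianSmooth(mi, window = 15)
  expect_equal(sum(si@mac), 1, tolerance = 1e-12)
  expect_equal(si@mac[16, 16], max(si@mac))
  ## window 1 is the identity
  expect_equal(gaussianSmooth(mi, window = 1, sigma = 1)@mac, imp)
})

test_that("phantom calibration ratios amplitudes into reflectance", {
  ph <- calibrationPhantom()
  mac <- matrix(runif(64, 100, 200), 8, 8)
  m <- new("DemodulatedMap", mac = mac, fx = 0, wavelength = 660,
           smoothed = TRUE)
  rdPh <- rdForward(0.019, 1.07, fx = 0)
  ## sample identical to phantom: rd is the phantom forward value
  expect_equal(calibrate(m, m, ph)@rd, matrix(rdPh, 8, 8), tolerance = 1e-12)
  ## linearity
  m2 <- new("DemodulatedMap", mac = 2 * mac, fx = 0, wavelength = 660,
            smoothed = TRUE)
  expect_equal(calibrate(m2, m, ph)@rd, matrix(2 * rdPh, 8, 8),
               tolerance = 1e-12)
  ## zero phantom amplitude errors with the affected pixel count
  bad <- m; bad@mac[1, 1] <- 0
  expect_error(calibrate(m, bad, ph), "1 pixel")
  mism <- new("DemodulatedMap", mac = mac, fx = 0.3, wavelength = 660,
              smoothed = TRUE)
  expect_error(calibrate(mism, m, ph), "fx")
})

test_that("reflectance lookup table covers the printed axes monotonically", {
  lut <- buildRdLut()
  expect_identical(dim(lut@rd0), c(512L, 512L))
  expect_equal(range(lut@muaAxis), c(1e-4, 0.2))
  expect_equal(range(lut@muspAxis), c(0.001, 3))
  expect_true(all(lut@rd0 > lut@rd03))
  expect_true(all(lut@rd0 > 0 & lut@rd0 < 1))
  ## darkest corner: strongest absorption, weakest scattering
  expect_equal(which.min(lut@rd0), which(lut@muaAxis == 0.2) +
                 0L * 512L)  # row 512, column 1
  expect_equal(min(lut@rd0), lut@rd0[512, 1])
})

test_that("optical property inversion round-trips interior media within 1%", {
  lut <- buildRdLut(nMua = 128L, nMusp = 128L)
  set.seed(42)
  for (i in seq_len(20)) {
    mua <- runif(1, 0.002, 0.18)
    musp <- runif(1, 0.2, 2.8)
    pr <- rdMapPair(mua, musp, dims = c(2L, 2L))
    opm <- invertOpticalProperties(pr$rd0, pr$rd3, lut)
    expect_false(any(opm@invalid))
    expect_lt(abs(opm@mua[1, 1] - mua) / mua, 0.01)
    expect_lt(abs(opm@musp[1, 1] - musp) / musp, 0.01)
  }
  ## grid-node identity
  mua <- lut@muaAxis[64]; musp <- lut@muspAxis[100]
  pr <- rdMapPair(mua, musp, dims = c(1L, 1L))
  opm <- invertOpticalProperties(pr$rd0, pr$rd3, lut)
  expect_equal(opm@mua[1, 1], mua, tolerance = 1e-6)
  expect_equal(opm@musp[1, 1], musp, tolerance = 1e-6)
})

test_that("unattainable reflectance pairs are flagged, not extrapolated", {
  lut <- buildRdLut(nMua = 64L, nMusp = 64L)
  mk <- function(v, fx) new("RdMap", rd = matrix(v, 2, 2), fx = fx,
                            wavelength = 660)
  expect_error(invertOpticalProperties(mk(0.99, 0), mk(0.99, 0.3), lut),
               "attainable")
  ## mixed map: valid pixel recovered, invalid pixel masked
  good <- rdMapPair(0.02, 1.0, dims = c(1L, 2L))
  r0 <- good$rd0; r0@rd[1, 2] <- 0.99
  r3 <- good$rd3; r3@rd[1, 2] <- 0.99
  opm <- invertOpticalProperties(r0, r3, lut)
  expect_false(opm@invalid[1, 1])
  expect_true(opm@invalid[1, 2])
  expect_true(is.na(opm@mua[1, 2]))
})

test_that("inversion is deterministic across repeated runs", {
  lut <- buildRdLut(nMua = 64L, nMusp = 64L)
  pr <- rdMapPair(0.033, 1.4, dims = c(3L, 3L))
  a <- invertOpticalProperties(pr$rd0, pr$rd3, lut)
  b <- invertOpticalProperties(pr$rd0, pr$rd3, lut)
  expect_identical(a@mua, b@mua)
  expect_identical(a@musp, b@musp)
})

test_that("processing the calibration phantom against itself returns its properties", {
  schedule <- makeSchedule(50)
  scene <- uniformScene(c(24L, 24L), calibrationPhantom(), db = 0)
  frames <- renderSfdiFrames(scene, schedule, noiseSd = 0)
  slots <- attr(frames, "slots")
  lut <- buildRdLut(nMua = 128L, nMusp = 128L)
  ph <- calibrationPhantom()
  for (wl in c(660, 780, 850)) {
    dem <- function(fx) {
      sl <- slots[slots$wavelength == wl & slots$fx == fx, ]
      sl <- sl[order(sl$phase), ]
      demodulate(phaseTriplet(frames[[sl$index[1] + 1]],
                              frames[[sl$index[2] + 1]],
                              frames[[sl$index[3] + 1]], fx, wl))
    }
    m0 <- dem(0); m3 <- dem(0.3)
    rd0 <- calibrate(m0, m0, ph)
    rd3 <- calibrate(m3, m3, ph)
    opm <- invertOpticalProperties(rd0, rd3, lut)
    i <- match(wl, ph@wavelength)
    expect_lt(max(abs(opm@mua - ph@mua[i]) / ph@mua[i]), 0.01)
    expect_lt(max(abs(opm@musp - ph@musp[i]) / ph@musp[i]), 0.01)
  }
})

test_that("chromophore fitting solves the extinction system", {
  ## identity system returns the absorption values as concentrations
  ident <- fitChromophores(list(matrix(0.01, 2, 2), matrix(0.03, 2, 2)),
                           diag(2))
  expect_equal(ident@cHbO2, matrix(0.01, 2, 2))
  expect_equal(ident@cHbR, matrix(0.03, 2, 2))
  ## equal concentrations give 50% saturation; additivity is exact
  E <- extinctionMatrix(c(660, 780, 850))
  cTrue <- list(hbo2 = matrix(60, 3, 3), hbr = matrix(60, 3, 3))
  muaMaps <- lapply(seq_len(3), function(i)
    E[i, 1] * cTrue$hbo2 + E[i, 2] * cTrue$hbr)
  ch <- fitChromophores(muaMaps, E)
  expect_equal(ch@sto2, matrix(50, 3, 3), tolerance = 1e-10)
  expect_equal(ch@hbt, ch@cHbO2 + ch@cHbR)
  ## overdetermined noise-free recovery to 1e-10
  cTrue <- list(hbo2 = matrix(runif(9, 20, 120), 3, 3),
                hbr = matrix(runif(9, 10, 80), 3, 3))
  muaMaps <- lapply(seq_len(3), function(i)
    E[i, 1] * cTrue$hbo2 + E[i, 2] * cTrue$hbr)
  ch <- fitChromophores(muaMaps, E)
  expect_equal(ch@cHbO2, cTrue$hbo2, tolerance = 1e-10)
  expect_equal(ch@cHbR, cTrue$hbr, tolerance = 1e-10)
  expect_true(all(ch@sto2 >= 0 & ch@sto2 <= 100))
  ## rank-deficient matrix is rejected
  expect_error(fitChromophores(muaMaps, cbind(E[, 1], E[, 1])), "rank")
})
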