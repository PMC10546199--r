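test_that("speckle synthesis is deterministic given the seed", {
  a <- simulateSpeckleStack(c(32L, 32L), frames = 2, tauC = 1e-3,
                            nSub = 8L, seed = 21)
  b <- simulateSpeckleStack(c(32L, 32L), frames = 2, tauC = 1e-3,
                            nSub = 8L, seed = 21)
  expect_identical(a, b)
  c <- simulateSpeckleStack(c(32L, 32L), frames = 2, tauC = 1e-3,
                            nSub = 8L, seed = 22)
  expect_false(identical(a, c))
  expect_error(simulateSpeckleStack(c(8L, 8L), frames = 1), "seed")
})

test_that("static fully developed speckle has unit intensity contrast", {
  st <- simulateSpeckleStack(c(192L, 192L), frames = 2, tauC = Inf,
                             specklePx = 4, bitDepth = NA, seed = 23)
  for (i in 1:2) {
    f <- st[, , i]
    expect_equal(stats::sd(f) / mean(f), 1, tolerance = 0.02)
  }
})

test_that("static speckle intensity is exponentially distributed", {
  st <- simulateSpeckleStack(c(256L, 256L), frames = 1, tauC = Inf,
                             specklePx = 4, bitDepth = NA, seed = 24)
  f <- st[, , 1]
  ## subsample far beyond the speckle correlation length for near-iid draws
  sub <- f[seq(1, 256, by = 13), seq(1, 256, by = 13)]
  ks <- stats::ks.test(as.vector(sub), "pexp", rate = 1 / mean(sub))
  expect_gt(ks$p.value, 0.01)
})

test_that("the tau_c match reproduces the correlation-diffusion contrast", {
  db <- 1e-6; mua <- 0.02; musp <- 1.0; nSub <- 32L; Texp <- 0.01
  tc <- tauCForDb(db, mua, musp, exposure = Texp, nSub = nSub)
  ti <- ((seq_len(nSub) - 0.5) / nSub) * Texp
  k2disc <- mean(exp(-abs(outer(ti, ti, "-")) / tc)^2)
  expect_equal(k2disc, k2Forward(db, mua, musp), tolerance = 1e-9)
  ## measured global contrast of a synthesized stack matches the model
  dy <- simulateSpeckleStack(c(192L, 192L), frames = 4, tauC = tc,
                             nSub = nSub, specklePx = 4, bitDepth = NA,
                             seed = 25)
  g <- vapply(1:4, function(i) {
    f <- dy[, , i]; stats::var(as.vector(f)) / mean(f)^2
  }, numeric(1))
  expect_equal(mean(g), k2Forward(db, mua, musp), tolerance = 0.05)
})

test_that("SFDI rendering is planar at fx = 0 and linear in modulation", {
  schedule <- makeSchedule(50)
  scene <- uniformScene(c(16L, 20L), calibrationPhantom(), db = 0)
  fr <- renderSfdiFrames(scene, schedule, noiseSd = 0)
  slots <- attr(fr, "slots")
  ## the three fx = 0 phases of one wavelength are identical images
  i660 <- slots$index[slots$wavelength == 660 & slots$fx == 0]
  expect_identical(fr[[i660[1] + 1]], fr[[i660[2] + 1]])
  expect_identical(fr[[i660[2] + 1]], fr[[i660[3] + 1]])
  ## doubling M0 doubles the demodulated AC amplitude
  fr2 <- renderSfdiFrames(scene, schedule, m0 = 20000, noiseSd = 0)
  iAc <- slots[slots$wavelength == 660 & slots$fx == 0.3, ]
  iAc <- iAc[order(iAc$phase), ]
  mac1 <- demodulate(phaseTriplet(fr[[iAc$index[1] + 1]],
                                  fr[[iAc$index[2] + 1]],
                                  fr[[iAc$index[3] + 1]], 0.3, 660))
  mac2 <- demodulate(phaseTriplet(fr2[[iAc$index[1] + 1]],
                                  fr2[[iAc$index[2] + 1]],
                                  fr2[[iAc$index[3] + 1]], 0.3, 660))
  expect_equal(mac2@mac, 2 * mac1@mac, tolerance = 1e-9)
  ## rendering with noise is reproducible under the seed
  n1 <- renderSfdiFrames(scene, schedule, noiseSd = 10, seed = 31)
  n2 <- renderSfdiFrames(scene, schedule, noiseSd = 10, seed = 31)
  expect_identical(n1, n2)
})

test_that("a noise-free rendering round-trips the scene optical properties", {
  schedule <- makeSchedule(50)
  scene <- phantomLibrary(dims = c(20L, 20L))$phantom2
  calScene <- uniformScene(c(20L, 20L), calibrationPhantom(), db = 0)
  fr <- renderSfdiFrames(scene, schedule, noiseSd = 0)
  cal <- renderSfdiFrames(calScene, schedule, noiseSd = 0)
  slots <- attr(fr, "slots")
  lut <- buildRdLut(nMua = 128L, nMusp = 128L)
  ph <- calibrationPhantom()
  dem <- function(frames, wl, fx) {
    sl <- slots[slots$wavelength == wl & slots$fx == fx, ]
    sl <- sl[order(sl$phase), ]
    demodulate(phaseTriplet(frames[[sl$index[1] + 1]],
                            frames[[sl$index[2] + 1]],
                            frames[[sl$index[3] + 1]], fx, wl))
  }
  for (wl in c(660, 850)) {
    rd0 <- calibrate(dem(fr, wl, 0), dem(cal, wl, 0), ph)
    rd3 <- calibrate(dem(fr, wl, 0.3), dem(cal, wl, 0.3), ph)
    opm <- invertOpticalProperties(rd0, rd3, lut)
    i <- match(wl, scene@wavelengths)
    muaTrue <- scene@mua[[i]][1, 1]
    muspTrue <- scene@musp[[i]][1, 1]
    expect_lt(max(abs(opm@mua - muaTrue)) / muaTrue, 0.01)
    expect_lt(max(abs(opm@musp - muspTrue)) / muspTrue, 0.01)
  }
})

test_that("the phantom library encodes the printed multiplicative relations", {
  lib <- phantomLibrary(dims = c(8L, 8L))
  expect_named(lib, c("phantom1", "phantom2", "phantom3", "phantom4"))
  for (w in seq_len(3)) {
    expect_equal(lib$phantom2@mua[[w]], 2 * lib$phantom1@mua[[w]])
    expect_equal(lib$phantom2@musp[[w]], lib$phantom1@musp[[w]])
    expect_equal(lib$phantom3@musp[[w]], 2 * lib$phantom1@musp[[w]])
    expect_equal(lib$phantom3@mua[[w]], lib$phantom1@mua[[w]])
    expect_equal(lib$phantom4@mua[[w]], 2 * lib$phantom1@mua[[w]])
    expect_equal(lib$phantom4@musp[[w]], 2 * lib$phantom1@musp[[w]])
    ## all four scenes stay inside the inversion table ranges
    for (p in lib) {
      expect_true(all(p@mua[[w]] >= 1e-4 & p@mua[[w]] <= 0.2))
      expect_true(all(p@musp[[w]] >= 0.001 & p@musp[[w]] <= 3))
    }
  }
  ## forward contrast ordering at fixed db (Brownian dynamics)
  k2s <- vapply(lib, function(p)
    k2Forward(1e-6, p@mua[[1]][1, 1], p@musp[[1]][1, 1]), numeric(1))
  expect_gt(k2s["phantom2"], k2s["phantom1"])
  expect_lt(k2s["phantom3"], k2s["phantom1"])
  expect_lt(abs(k2s["phantom4"] - k2s["phantom1"]) / k2s["phantom1"], 1e-9)
})

test_that("flow-tube scenes confine elevated Db to the tube band", {
  sc <- flowTubeScene(c(24L, 24L), dbTube = 2e-6)
  expect_equal(sort(unique(as.vector(sc@db))), c(0, 2e-6))
  mid <- sc@db[, 12]
  expect_true(all(mid == 2e-6))
  expect_true(all(sc@db[, 1] == 0))
})
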