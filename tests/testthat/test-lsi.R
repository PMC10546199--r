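test_that("sliding-window contrast matches a brute-force oracle", {
  set.seed(7)
  f <- matrix(rexp(64 * 64, 1 / 60), 64, 64)
  cm <- speckleContrast(f, window = 5, exposure = 0.01)
  ij <- cbind(sample(3:62, 50, replace = TRUE), sample(3:62, 50, replace = TRUE))
  for (r in seq_len(nrow(ij))) {
    expect_equal(cm@k[ij[r, 1], ij[r, 2]],
                 bruteWindowContrast(f, ij[r, 1], ij[r, 2]),
                 tolerance = 1e-12)
  }
})

test_that("contrast is zero for constants, scale invariant, and flags borders", {
  f <- matrix(42, 16, 16)
  cm <- speckleContrast(f)
  expect_true(all(cm@k[!cm@invalid] == 0))
  ## 2-pixel border of a 5x5 window is invalid, not padded
  expect_true(all(cm@invalid[1:2, ]))
  expect_true(all(cm@invalid[, 15:16]))
  expect_false(any(cm@invalid[3:14, 3:14]))
  ## intensity-scale invariance
  set.seed(8)
  g <- matrix(rexp(400, 1 / 50), 20, 20)
  k1 <- speckleContrast(g)@k
  k2 <- speckleContrast(g * 7.3)@k
  expect_lt(max(abs(k1 - k2), na.rm = TRUE), 1e-12)
  ## an all-zero window is flagged invalid
  z <- matrix(0, 16, 16); z[12:16, 12:16] <- 100
  cz <- speckleContrast(z)
  expect_true(cz@invalid[5, 5])
  expect_true(is.na(cz@k[5, 5]))
  expect_error(speckleContrast(matrix(-1, 8, 8)), "non-negative")
})

test_that("temporally pooled contrast reduces to the single-frame estimator", {
  set.seed(9)
  f <- matrix(rexp(900, 1 / 30), 30, 30)
  one <- speckleContrast(f)
  pooled <- cycleContrast(list(f))
  expect_equal(pooled@k, one@k, tolerance = 1e-12)
  ## constant stack gives zero contrast
  cc <- cycleContrast(array(5, c(12, 12, 3)))
  expect_true(all(cc@k[!cc@invalid] == 0))
})

test_that("speckle flow index follows the 1/(2TK^2) law", {
  expect_equal(mapValues(sfi(constantContrast(1, exposure = 0.01)))[1, 1], 50)
  expect_equal(mapValues(sfi(constantContrast(0.5, exposure = 0.01)))[1, 1],
               200)
  ## halving K quadruples SFI
  s1 <- mapValues(sfi(constantContrast(0.4)))[1, 1]
  s2 <- mapValues(sfi(constantContrast(0.2)))[1, 1]
  expect_equal(s2 / s1, 4, tolerance = 1e-12)
  ## zero contrast (infinite flow) is flagged
  z <- sfi(constantContrast(0))
  expect_true(all(invalidMask(z)))
})

test_that("beta estimation squares the ROI median contrast and resists outliers", {
  expect_equal(estimateBeta(constantContrast(0.6))@beta, 0.36)
  expect_equal(estimateBeta(constantContrast(1))@beta, 1)
  ## < 50% contamination leaves the median-based estimate unchanged
  k <- matrix(0.6, 10, 10)
  k[1:4, ] <- 5  # 40% wild outliers
  cm <- new("ContrastMap", k = k, exposure = 0.01, window = 5,
            invalid = matrix(FALSE, 10, 10))
  expect_equal(estimateBeta(cm)@beta, 0.36)
  expect_error(estimateBeta(constantContrast(0.6),
                            roi = matrix(FALSE, 8, 8)), "no valid")
})

test_that("beta correction scales flow maps and cancels under normalization", {
  f <- sfi(constantContrast(0.5))            # 200 s^-1
  expect_equal(mapValues(betaCorrect(f, 1)), mapValues(f))
  expect_equal(mapValues(betaCorrect(f, 0.36))[1, 1], 72, tolerance = 1e-12)
  ## normalized time courses are invariant to beta
  series <- c(200, 220, 180, 240)
  n1 <- series / series[1]
  n2 <- (0.36 * series) / (0.36 * series[1])
  expect_equal(n1, n2)
})

test_that("ROI time courses median-filter correctly", {
  mk <- function(v) matrix(v, 9, 9)
  roi <- circularRoi(c(9, 9), radius = 3)
  ## constant series unchanged at any filter length
  maps <- lapply(rep(2.5, 6), mk)
  expect_equal(roiTimecourse(maps, roi, filterLen = 4), rep(2.5, 6))
  ## filterLen 1 returns the raw medians
  maps <- lapply(1:5, mk)
  expect_equal(roiTimecourse(maps, roi, filterLen = 1), 1:5)
  ## step response ramps over the moving-average support
  step <- lapply(c(0, 0, 0, 0, 1, 1, 1, 1), mk)
  out <- roiTimecourse(step, roi, filterLen = 4)
  expect_equal(out[2:6], c(0, 0.25, 0.5, 0.75, 1))
  expect_error(roiTimecourse(maps, roi, filterLen = 10), "exceeds")
  ## invalid pixels are excluded from the median
  cm <- constantContrast(0.5, dims = c(9L, 9L))
  cm@k[5, 5] <- 99; cm@invalid[5, 5] <- TRUE
  expect_equal(roiTimecourse(list(cm), roi), 0.5)
})

test_that("contrast falls and SFI rises across a decorrelation staircase", {
  tcs <- c(Inf, 2e-2, 2e-3, 2e-4)
  med <- vapply(seq_along(tcs), function(i) {
    st <- simulateSpeckleStack(c(96L, 96L), frames = 2, tauC = tcs[i],
                               nSub = 16L, seed = 100 + i)
    cm <- cycleContrast(list(st[, , 1], st[, , 2]))
    stats::median(cm@k[!cm@invalid])
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  sfiMed <- 1 / (2 * 0.01 * med^2)
  expect_true(all(diff(sfiMed) > 0))
})
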