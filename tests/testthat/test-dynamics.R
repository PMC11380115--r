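test_that("autocorrelation matches the brute-force correlator and closed forms", {
  set.seed(1)
  series <- rpois(256, 40) + 0.0
  cc <- autocorrelate(series, 0.002)
  oracle <- directAutocorr(series, round(cc@lags / 0.002))
  expect_lt(max(abs(cc@G - oracle)), 1e-10)
  # constant series: zero fluctuations, G identically zero
  con <- autocorrelate(rep(7, 128), 0.01)
  expect_true(all(con@G == 0))
  # zero-mean series rejected
  expect_error(autocorrelate(rep(c(-1, 1), 64), 0.01), "zero-mean")
  expect_error(autocorrelate(1:32, 0.01), "64")
})

test_that("a cosine-modulated series correlates to the analytic cosine", {
  A <- 10; B <- 2; f <- 1 / 16; n <- 256
  t <- 0:(n - 1)
  series <- A + B * cos(2 * pi * f * t)
  # at lags multiple of 8 the finite-sum cross terms cancel exactly
  lags <- c(8L, 16L, 24L, 32L)
  cc <- autocorrelate(series, 1, lagScheme = lags)
  expect_equal(cc@G, (B^2 / (2 * A^2)) * cos(2 * pi * f * lags),
               tolerance = 1e-10)
})

test_that("the normalized estimator is scale invariant and multi-tau matches direct lags", {
  set.seed(2)
  series <- rpois(4096, 30) + 0.0
  a <- autocorrelate(series, 0.002)
  b <- autocorrelate(3.7 * series, 0.002)
  expect_equal(a@G, b@G, tolerance = 1e-12)
  direct <- directAutocorr(series, round(a@lags / 0.002))
  expect_lt(max(abs(a@G - direct)), 1e-8)
  # multi-tau lags are pseudo-logarithmic: strictly increasing spacing
  spacing <- diff(round(a@lags / 0.002))
  expect_true(all(diff(spacing) >= 0))
})

test_that("FCS fits recover clean and noisy single-component curves", {
  lags <- (1:200) * 1e-3
  G0 <- 0.1; tauD <- 0.010
  clean <- new("CorrelationCurve", lags = lags,
               G = G0 / (1 + lags / tauD),
               samplesPerLag = 5000 - seq_along(lags),
               frameInterval = 1e-3)
  fit <- fitFcs(clean, "brownian1")
  expect_true(fit@converged)
  expect_equal(fit@G0, G0, tolerance = 1e-6)
  expect_equal(fit@tauD, tauD, tolerance = 1e-6)
  # 5% rms noise: tauD within 10% in the median over 100 draws
  set.seed(3)
  taus <- replicate(100, {
    noisy <- clean
    noisy@G <- clean@G + rnorm(length(lags), 0, 0.05 * G0)
    f <- fitFcs(noisy, "brownian1")
    if (f@converged) f@tauD else NA
  })
  expect_equal(median(taus, na.rm = TRUE), tauD, tolerance = 0.1)
  # anomalous fit with alpha fixed at 1 collapses to brownian1
  fitA <- fitFcs(clean, "anomalous", fixedAlpha = 1)
  expect_equal(fitA@tauD, fit@tauD, tolerance = 1e-6)
})

test_that("two-component fits separate well-split diffusion times", {
  lags <- (1:400) * 1e-3
  G <- 0.2 * (0.7 / (1 + lags / 0.004) + 0.3 / (1 + lags / 0.08))
  curve <- new("CorrelationCurve", lags = lags, G = G,
               samplesPerLag = rep(4000, length(lags)),
               frameInterval = 1e-3)
  fit <- fitFcs(curve, "brownian2")
  expect_true(fit@converged)
  expect_equal(fit@fraction, 0.7, tolerance = 0.01)
  expect_equal(fit@tauD, 0.004, tolerance = 0.01)
  expect_equal(fit@tauD2, 0.08, tolerance = 0.01)
})

test_that("diffusion maps apply D = omega^2 / (4 tauD) with honest masking", {
  dm <- diffusionMap(matrix(0.005, 2, 2), omega = 0.3)
  expect_true(all(dm@D == 4.5))
  # doubling tauD halves D
  dm2 <- diffusionMap(matrix(0.010, 2, 2), omega = 0.3)
  expect_equal(dm2@D, dm@D / 2)
  # invalid entries masked, never propagated
  td <- matrix(c(0.005, -1, NA, 0.02), 2, 2)
  dm3 <- diffusionMap(td, omega = 0.3)
  expect_equal(dm3@validMask, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_true(all(is.na(dm3@D[!dm3@validMask])))
  expect_error(diffusionMap(td, omega = 0), "omega")
})

test_that("SOFI cross-correlation rejects independent noise and shares split sources", {
  set.seed(4)
  T <- 4000
  # independent noise at neighbouring pixels: XC below the statistical bound
  mov <- array(rnorm(T * 4 * 4, 100, 5), c(T, 4, 4))
  s <- sofiXc2(mov, 1)
  virtuals <- s@values[seq(2, 6, 2), seq(1, 7, 2)]
  expect_lt(max(abs(virtuals)), 3 * 25 / sqrt(T))
  # one slow blinking source split between two neighbours with weights w1, w2
  w1 <- 0.7; w2 <- 0.3
  src <- 50 * rep(rbinom(T / 20, 1, 0.5), each = 20) # slow telegraph
  mv2 <- array(0, c(T, 2, 3))
  mv2[, 1, 2] <- w1 * src + 20
  mv2[, 2, 2] <- w2 * src + 20
  s2 <- sofiXc2(mv2, 1)
  dSrc <- src - mean(src)
  lag1 <- mean(dSrc[1:(T - 1)] * dSrc[2:T])
  xc <- s2@values[2, 3] # midpoint between the two loaded pixels
  expect_equal(xc, w1 * w2 * lag1, tolerance = 0.05)
  # static movie: all values zero
  s3 <- sofiXc2(array(5, c(10, 3, 3)), 1)
  expect_true(all(s3@values == 0))
  expect_error(sofiXc2(array(1, c(4, 3, 3)), 4), "lag")
})

test_that("SOFI sharpens a blinking point source beyond the mean image", {
  set.seed(5)
  T <- 2000
  blink <- rep(rbinom(T / 4, 1, 0.5), each = 4)
  frame <- gaussianFrame(15, 15, c(7.2, 7.2), sigma = 2, amplitude = 100)
  mov <- array(0, c(T, 15, 15))
  for (t in seq_len(T)) mov[t, , ] <- frame * blink[t]
  s <- sofiXc2(mov, 1, gridKind = "native")
  meanImg <- colMeans(mov)
  fwhmSofi <- sigmaToFwhm(profileSigma(s@values[8, ]))
  fwhmMean <- sigmaToFwhm(profileSigma(meanImg[8, ]))
  expect_lt(fwhmSofi, fwhmMean)
  expect_equal(fwhmSofi, fwhmMean / sqrt(2), tolerance = 0.05)
})

test_that("fusion maps log-diffusion to hue and SOFI to value", {
  vals <- matrix(c(0, 0.5, 1, 2), 2, 2)
  sofi <- new("SofiImage", values = vals, gridKind = "native",
              clampFraction = 0)
  # uniform D: uniform hue
  dm <- diffusionMap(matrix(0.01, 2, 2), omega = 0.3)
  fused <- fuseImages(sofi, dm)
  expect_equal(length(unique(as.vector(fused@hue))), 1L)
  # SOFI = 0 pixel renders black
  expect_true(all(fused@rgb[1, 1, ] == 0))
  # hue is monotone in log10(D) across the range
  Ds <- 10^seq(-1, 2, length.out = 7)
  dmSweep <- diffusionMap(matrix(0.3^2 / (4 * Ds), 1, 7), omega = 0.3)
  sofiOne <- new("SofiImage", values = matrix(1, 1, 7),
                 gridKind = "native", clampFraction = 0)
  hues <- fuseImages(sofiOne, dmSweep)@hue
  expect_true(all(diff(as.vector(hues)) < 0) ||
                all(diff(as.vector(hues)) > 0))
  # invalid pixels are rendered unsaturated
  dmBad <- diffusionMap(matrix(c(0.01, NA, 0.01, 0.01), 2, 2), omega = 0.3)
  fused2 <- fuseImages(sofi, dmBad)
  expect_equal(fused2@saturation[2, 1], 0)
  expect_error(fuseImages(sofi, diffusionMap(matrix(NA_real_, 2, 2), 0.3)),
               "valid")
})

test_that("the fcsSOFI slice pipeline masks immobile scenes and keeps shape", {
  set.seed(6)
  # immobile emitters + noise: no decaying correlation, fully masked
  frame <- gaussianFrame(12, 12, rbind(c(4, 4), c(8, 8)), 1.5,
                         amplitude = 200)
  mov <- array(0, c(400, 12, 12))
  for (t in 1:400) mov[t, , ] <- frame
  mov <- addCameraNoise(mov, NoiseModel("scmos", readNoise = 2,
                                        offset = 100), seed = 1)
  res <- fcsSofiSlice(mov, 0.002, omega = 0.5)
  expect_equal(sum(res$dmap@validMask), 0L)
  expect_null(res$fused)
  expect_equal(dim(res$sofi@values), c(23, 23)) # interleaved 2x grid
  expect_equal(dim(res$dmap@D), c(12, 12))
})

test_that("two-region movies order their recovered diffusion medians", {
  geom <- AcquisitionGeometry(sheetAngle = 66, zStep = 5,
                              pixelSize = 0.1625, fov = c(24, 12))
  mkMovie <- function(D, seed)
    simulateDiffusionMovie(
      DiffusionSimSpec(nWalkers = 30, D = D, frameInterval = 0.002,
                       nFrames = 3000, brightness = 300, seed = seed),
      geom, psfSigma = 0.25,
      noise = NoiseModel("scmos", readNoise = 1.6, offset = 100))
  # two regions simulated side by side: slow left, fast right
  slow <- mkMovie(2, 21)[, , 1:12]
  fast <- mkMovie(10, 22)[, , 13:24]
  mov <- array(0, c(3000, 12, 24))
  mov[, , 1:12] <- slow
  mov[, , 13:24] <- fast
  res <- fcsSofiSlice(mov, 0.002, omega = 0.5)
  mSlow <- median(res$dmap@D[, 1:12][res$dmap@validMask[, 1:12]])
  mFast <- median(res$dmap@D[, 13:24][res$dmap@validMask[, 13:24]])
  expect_lt(mSlow, mFast)
  expect_gte(mFast / mSlow, 2)
})
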