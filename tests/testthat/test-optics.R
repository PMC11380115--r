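test_that("Gaussian intensity satisfies the 1/e^2 waist definition and is radially symmetric", {
  b <- GaussianBeamSpec(wavelength = 0.532, waist = 4)
  ratio <- gaussianIntensity(b, r = 4, z = 0) /
    gaussianIntensity(b, r = 0, z = 0)
  expect_equal(ratio, exp(-2), tolerance = 1e-12)
  r <- c(0.3, 1.7, 5.2)
  z <- c(-40, 0, 95)
  for (zz in z)
    expect_equal(gaussianIntensity(b, r, zz), gaussianIntensity(b, -r, zz))
  expect_error(gaussianIntensity(b, NaN, 0), "finite")
  # peak normalization: on-axis waist intensity equals the amplitude
  expect_equal(gaussianIntensity(b, 0, 0, normalize = "peak"), 1)
})

test_that("Gaussian transverse power is conserved along z", {
  b <- GaussianBeamSpec(wavelength = 0.532, waist = 4)
  zR <- gaussianPropagation(b)$rayleighRange
  power <- function(z)
    integrate(function(r) gaussianIntensity(b, r, z) * 2 * pi * r,
              0, Inf, rel.tol = 1e-10)$value
  for (z in c(zR, 2.5 * zR, -0.7 * zR))
    expect_equal(power(z) / power(0), 1, tolerance = 1e-6)
})

test_that("Gaussian propagation parameters match the closed forms", {
  b <- GaussianBeamSpec(wavelength = 0.532, waist = 4)
  p <- gaussianPropagation(b)
  # confocal parameter ~189 um for a 4 um waist at 532 nm (the published
  # figure quotes 'roughly 200 um' for this configuration)
  expect_equal(p$confocalParameter, 2 * pi * 16 / 0.532, tolerance = 1e-12)
  expect_equal(round(p$confocalParameter), 189)
  expect_equal(p$radiusAt(0), 4)
  expect_equal(p$radiusAt(p$rayleighRange), 4 * sqrt(2))
  # doubling the waist quadruples the Rayleigh range
  b2 <- GaussianBeamSpec(wavelength = 0.532, waist = 8)
  expect_equal(gaussianPropagation(b2)$rayleighRange, 4 * p$rayleighRange)
  expect_equal(waistFromDivergence(0.532, 0.1), 1.693, tolerance = 1e-3)
  expect_error(waistFromDivergence(0.532, 0), "divergence")
})

test_that("confocal parameter scales quadratically in waist and inversely in wavelength", {
  set.seed(42)
  for (i in 1:20) {
    w <- runif(1, 0.5, 10); lam <- runif(1, 0.4, 0.7)
    a <- runif(1, 1.1, 3)
    bg <- function(w, l)
      gaussianPropagation(GaussianBeamSpec(l, w))$confocalParameter
    expect_equal(bg(a * w, lam), a^2 * bg(w, lam), tolerance = 1e-10)
    expect_equal(bg(w, a * lam), bg(w, lam) / a, tolerance = 1e-10)
  }
})

test_that("Bessel beam: confocal parameter, on-axis maximum and first radial zero", {
  expect_equal(besselConfocal(6, 0.03), 199.9, tolerance = 1e-3)
  expect_error(besselConfocal(6, 0), "alpha0")
  ax <- AxiconSpec(refractiveIndex = 1.45, alpha0 = 0.03)
  r <- seq(0, 30, by = 0.05)
  prof <- besselProfile(6, ax, 0.532, r, z = 50)
  expect_equal(which.max(prof), 1L) # J0^2 maximal at r = 0
  # first zero of J0 located by bracketing the series expansion
  k <- 2 * pi / 0.532
  j0root <- uniroot(function(x) j0Series(x), c(2, 3), tol = 1e-10)$root
  expect_equal(j0root, 2.40483, tolerance = 1e-5)
  rZero <- j0root / (k * sin(0.03))
  profNearZero <- besselProfile(6, ax, 0.532, rZero, z = 50)
  expect_lt(profNearZero / max(prof), 1e-8)
})

test_that("Airy function and beam profile behave as the closed form dictates", {
  # Ai on the real axis against the modified-Bessel closed form
  x <- c(0.2, 0.7, 1.5, 3, 5)
  ref <- (1 / pi) * sqrt(x / 3) * besselK(2 * x^1.5 / 3, 1 / 3)
  expect_equal(airyAi(x), ref, tolerance = 1e-12)
  # a = 0, z = 0 reduces to Ai^2(x/x0) Ai^2(y/x0)
  sp <- AirySpec(characteristicLength = 1, apodization = 0,
                 wavelength = 0.532)
  xs <- c(-2, -0.5, 0.3, 1)
  expect_equal(airyProfile(sp, xs, 0.4, 0),
               airyAi(xs)^2 * airyAi(0.4)^2, tolerance = 1e-10)
  # x <-> y symmetry with apodization and defocus
  sp2 <- AirySpec(1.5, apodization = 0.1, wavelength = 0.532)
  expect_equal(airyProfile(sp2, 0.8, -0.3, 5),
               airyProfile(sp2, -0.3, 0.8, 5), tolerance = 1e-12)
  # propagation length under the implemented grouping (hand arithmetic)
  expect_equal(airyPropagation(1.2, 5, 1, 0.532),
               0.5 * sqrt(2 * log(2)) * 2 * pi * 1 * 1.2^2 / (5 * 0.532),
               tolerance = 1e-12)
})

test_that("lens-train propagation follows the focused-diameter relation", {
  # collimated 0.57 mm radius input through a single f = 50 mm lens
  beam <- GaussianBeamSpec(wavelength = 0.532, waist = 570)
  tr <- propagateTrain(beam, list(LensElement(50)))
  expect_equal(tr$sheetWidth, 4 * 50e3 * 0.532 / (pi * 570),
               tolerance = 1e-12)
  expect_equal(round(tr$sheetWidth, 1), 59.4)
  # an x-only cylindrical element leaves the y axis bitwise unchanged
  tr2 <- propagateTrain(beam, list(LensElement(50, axis = "x_only")))
  expect_identical(tr2$perElement$axis_y_waist_um, beam@waist)
  # all-spherical trains keep both axes equal at every stage
  tr3 <- propagateTrain(beam, list(LensElement(100), LensElement(50, 30),
                                   LensElement(25, 10)))
  expect_equal(tr3$perElement$axis_x_waist_um,
               tr3$perElement$axis_y_waist_um)
  expect_equal(tr3$sheetWidth, tr3$sheetThickness)
})

test_that("objective resolution reproduces the published worked examples", {
  r1 <- objectiveResolution(ObjectiveSpec(100, 1.5, immersionIndex = 1.52),
                            532)
  expect_equal(r1$lateral, 177, tolerance = 0.005)
  expect_equal(r1$axial, 473, tolerance = 0.005)
  r2 <- objectiveResolution(ObjectiveSpec(40, 0.65, immersionIndex = 1),
                            532)
  expect_equal(r2$lateral, 409, tolerance = 0.005)
  expect_equal(r2$axial, 2520, tolerance = 0.005)
  expect_equal(objectiveResolution(ObjectiveSpec(40, 0.8), 532)$fobj, 5)
  expect_error(objectiveResolution(ObjectiveSpec(40, 0.8), 532)$na <-
                 objectiveResolution(ObjectiveSpec(40, 0), 532),
               "numericalAperture|aperture")
})

test_that("resolution is strictly decreasing in NA", {
  set.seed(7)
  nas <- sort(runif(10, 0.2, 1.3))
  res <- vapply(nas, function(na)
    unlist(objectiveResolution(ObjectiveSpec(40, na, immersionIndex = 1.33),
                               575)[c("lateral", "axial")]), numeric(2))
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("system PSF is the elementwise product with documented renormalization", {
  g3 <- function(s) {
    k <- psfKernel(buildPsf3d(sigmaToFwhm(s), sigmaToFwhm(s),
                              c(15, 15, 15)))
    k
  }
  a <- g3(1.5); ones <- array(1, dim(a))
  expect_equal(lsmPsf(a, ones, renormalize = FALSE), a)
  b <- g3(2.5)
  expect_equal(lsmPsf(a, b), lsmPsf(b, a))
  expect_error(lsmPsf(a, array(1, c(3, 3, 3))), "shape")
  # product of isotropic Gaussians sigma1, sigma2 -> sigma combined
  prod <- lsmPsf(a, b)
  sComb <- (1.5^-2 + 2.5^-2)^(-0.5)
  mid <- prod[, 8, 8]
  expect_equal(profileSigma(mid), sComb, tolerance = 0.01)
  # never exceeds the elementwise min of max-normalized inputs
  expect_true(all(prod / max(prod) <= pmin(a / max(a), b / max(b)) + 1e-12))
})

test_that("pixel geometry and expected bead extent match the published numbers", {
  expect_equal(pixelGeometry(6.5, magnification = 40)$imagePixel, 0.1625)
  expect_equal(pixelGeometry(6.5, magnification = 40)$imagePixel, 0.163,
               tolerance = 0.0035) # prints as 0.163 at the paper's precision
  expect_equal(pixelGeometry(13, targetPixelSize = 0.1)$requiredMagnification,
               130)
  expect_equal(expectedBeadPsfPx(2.10, 0.1625), 12.9, tolerance = 0.005)
  expect_error(pixelGeometry(6.5, magnification = 0), "magnification")
})

test_that("depth of field reproduces the worked example and limits", {
  expect_equal(depthOfField(575, 1.33, 0.8, 0.1625, 40), 1.20,
               tolerance = 0.005)
  expect_equal(depthOfField(575, 1.33, 0.8, 0, 40), 0.575 * 1.33 / 0.64)
  expect_equal(depthOfField(532, 1.0, 0.95, 0.1, 60), 0.591,
               tolerance = 0.001)
  expect_error(depthOfField(575, 1.33, 0, 0.1625, 40), "numericalAperture")
})
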