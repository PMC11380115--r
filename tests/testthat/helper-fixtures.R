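# Fixture builders and independent oracles shared across the suite.

# dense direct evaluation of Gaussian spots (independent of the package's
# supersampled renderer): pixel value = amplitude * exp(-d^2 / 2 sigma^2)
# at the pixel centre, 0-based coordinates
gaussianFrame <- function(nr, nc, centers, sigma, amplitude = 100,
                          background = 0) {
  img <- matrix(background, nr, nc)
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  centers <- matrix(centers, ncol = 2) # (x=col, y=row)
  for (i in seq_len(nrow(centers)))
    img <- img + amplitude *
      exp(-((rr - centers[i, 2])^2 + (cc - centers[i, 1])^2) /
            (2 * sigma^2))
  img
}

# brute-force O(N^2) normalized autocorrelation oracle
directAutocorr <- function(series, lagsFrames) {
  n <- length(series)
  mu <- mean(series)
  dF <- series - mu
  vapply(lagsFrames, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + dF[t] * dF[t + k]
    s / ((n - k) * mu^2)
  }, numeric(1))
}

# partial-sum series expansion of the Bessel function J0 (oracle,
# independent of base R's besselJ)
j0Series <- function(x, nTerms = 60) {
  out <- 0
  term <- 1
  for (k in 0:nTerms) {
    if (k > 0) term <- term * (-(x^2) / 4) / k^2
    out <- out + term
  }
  out
}

# moment-based sd of a 1D profile (oracle for FWHM checks)
profileSigma <- function(y) {
  x <- seq_along(y) - 1
  m <- sum(x * y) / sum(y)
  sqrt(sum(y * (x - m)^2) / sum(y))
}

testGeometry <- function(fov = c(96, 96), zStep = 2, sheetAngle = 66,
                         pixelSize = 0.1625, skewPerUm = NULL) {
  AcquisitionGeometry(sheetAngle = sheetAngle, zStep = zStep,
                      pixelSize = pixelSize, fov = fov,
                      skewPerUm = skewPerUm)
}

# thick sheet keeps beads visible across several slices for tracking tests
thickSheet <- function() SheetProfile(thickness = 12, width = 20)
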