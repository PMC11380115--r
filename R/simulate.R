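## Synthetic acquisition simulator: bead phantoms and Brownian-diffusion
## movies rendered through a tilted-sheet forward model (sheet weighting,
## Gaussian detection PSF, per-slice skew, camera noise). All randomness
## flows from explicit per-call seeds; no global RNG state is consumed.

# Render Gaussian spots onto an image by 4x supersampling + area binning.
# posRow/posCol are 0-based pixel-centre coordinates; photons is the
# integrated expected photon count per spot; sigmaPx the spot sd in pixels.
# Supersampling (rather than centre sampling) keeps sub-pixel centroids
# stable for calibration tests.
.renderSpots <- function(nRows, nCols, posRow, posCol, sigmaPx, photons,
                         supersample = 4L) {
  img <- matrix(0, nRows, nCols)
  if (!length(posRow)) return(img)
  sub <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  for (i in seq_along(posRow)) {
    s <- sigmaPx[i]
    if (photons[i] <= 0) next
    halfw <- ceiling(4 * s + 1)
    r0 <- max(0, floor(posRow[i]) - halfw)
    r1 <- min(nRows - 1, ceiling(posRow[i]) + halfw)
    c0 <- max(0, floor(posCol[i]) - halfw)
    c1 <- min(nCols - 1, ceiling(posCol[i]) + halfw)
    if (r1 < r0 || c1 < c0) next
    rows <- r0:r1; cols <- c0:c1
    # separable Gaussian: per-axis means over the supersample offsets
    vr <- rowMeans(exp(-outer(rows - posRow[i], sub, "+")^2 / (2 * s^2)))
    vc <- rowMeans(exp(-outer(cols - posCol[i], sub, "+")^2 / (2 * s^2)))
    amp <- photons[i] / (2 * pi * s^2)
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + amp * outer(vr, vc)
  }
  img
}

#' Generate a random bead phantom
#'
#' Uniformly random bead positions within a rectangular volume with
#' truncated-normal diameters (> 0 by construction). Emulates a fluorescent
#' bead calibration standard suspended in an index-matched hydrogel.
#'
#' @param n number of beads (>= 0)
#' @param diameterMean,diameterSd bead diameter distribution (micrometres)
#' @param volumeDims c(X, Y, Z) volume extents (micrometres)
#' @param brightness expected photons per frame for a bead centred in the
#'   sheet (integrated over the spot)
#' @param seed integer seed; identical seeds give identical phantoms
#' @return A \code{\link{BeadPhantom}}.
#' @examples
#' makeBeadPhantom(10, 2.1, 0.09, c(50, 50, 50), 2e4, seed = 1)
#' @export
makeBeadPhantom <- function(n, diameterMean, diameterSd, volumeDims,
                            brightness = 1e4, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  .withSeed(seed, {
    pos <- cbind(runif(n, 0, volumeDims[1]), runif(n, 0, volumeDims[2]),
                 runif(n, 0, volumeDims[3]))
    dia <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) { # truncate at zero by resampling
      dia[todo] <- rnorm(length(todo), diameterMean, diameterSd)
      todo <- todo[dia[todo] <= 0]
    }
    new("BeadPhantom", positions = pos, diameters = dia,
        brightness = brightness, volumeDims = as.numeric(volumeDims))
  })
}

#' Render a bead phantom into a stage-scanned z-stack
#'
#' Forward model of tilted-sheet acquisition. For stage position k * zStep
#' (k = 0, 1, ...), each bead is weighted by the sheet's Gaussian axial
#' profile at its distance from the sheet plane, shifted laterally by
#' (k * zStep * sx, k * zStep * sy) -- the ground-truth skew -- blurred by
#' the detection PSF combined with the bead's own extent (a bead of diameter
#' b is rendered as a Gaussian blob of FWHM b before PSF blur), rasterized at
#' the image pixel size by 4x supersampling and area binning, and camera
#' noise is applied per frame.
#'
#' @param phantom a \code{\link{BeadPhantom}}
#' @param geometry an \code{\link{AcquisitionGeometry}}
#' @param sheet a \code{\link{SheetProfile}}
#' @param psfSigma lateral sd of the detection PSF at the sample plane
#'   (micrometres), or a \code{\link{PSF3D}} whose lateral FWHM (pixels) is
#'   converted via the pixel size
#' @param nSlices number of z slices; default covers the phantom depth
#' @param exposureFrames frames recorded per slice
#' @param noise a \code{\link{NoiseModel}}
#' @param seed integer seed for the noise draws
#' @return An \code{\link{ImageStack}} whose \code{meta$groundTruth} records
#'   the generating skew, bead positions and slice planes.
#' @export
renderAcquisition <- function(phantom, geometry, sheet, psfSigma = 0.25,
                              nSlices = NULL, exposureFrames = 1L,
                              noise = NoiseModel("none", offset = 0),
                              seed = NULL) {
  nCols <- as.integer(geometry@fov[1]); nRows <- as.integer(geometry@fov[2])
  if (nCols < 1 || nRows < 1) stop("empty field of view")
  pi_um <- geometry@pixelSize
  if (is(psfSigma, "PSF3D"))
    psfSigma <- fwhmToSigma(psfSigma@lateralFwhm) * pi_um
  if (is.null(nSlices))
    nSlices <- max(1L, ceiling(phantom@volumeDims[3] / geometry@zStep) + 1L)
  sx <- geometry@skewPerUm[1]; sy <- geometry@skewPerUm[2]
  sigBead <- fwhmToSigma(phantom@diameters)
  sigPx <- sqrt(psfSigma^2 + sigBead^2) / pi_um
  data <- array(0, c(nSlices, exposureFrames, nRows, nCols))
  .withSeed(seed, {
    for (k in seq_len(nSlices) - 1L) {
      zk <- k * geometry@zStep
      w <- sheetAxialWeight(sheet, phantom@positions[, 3] - zk)
      col <- (phantom@positions[, 1] + zk * sx) / pi_um
      row <- (phantom@positions[, 2] + zk * sy) / pi_um
      keep <- w > 1e-6
      photon <- .renderSpots(nRows, nCols, row[keep], col[keep],
                             sigPx[keep], phantom@brightness * w[keep])
      for (f in seq_len(exposureFrames))
        data[k + 1L, f, , ] <- addCameraNoise(photon, noise)
    }
  })
  stk <- ImageStack(data, pixelSize = pi_um, zStep = geometry@zStep,
                    frameInterval = 0.002)
  stk@meta$groundTruth <- list(skewPerUm = c(sx, sy),
                               positions = phantom@positions,
                               slicePlanes = (seq_len(nSlices) - 1) *
                                 geometry@zStep,
                               psfSigma = psfSigma)
  stk
}

#' Simulate a movie of Brownian point emitters
#'
#' Walkers take per-frame Gaussian steps of per-axis sd sqrt(2 D dt) within
#' the field of view (in-plane motion within the sheet), reflect at the
#' boundaries, and honour an optional porous region mask by rejecting steps
#' into closed pixels. Each emitter is rendered as a 2D Gaussian spot of the
#' given PSF sd; camera noise is applied per frame. Emulates a high-molecular
#' weight tracer (e.g. 155 kDa dextran) diffusing in an agarose gel.
#'
#' @param spec a \code{\link{DiffusionSimSpec}}; \code{nWalkers} is the
#'   expected number of walkers within the field of view (the simulation
#'   domain extends \code{marginUm} beyond the FOV at matched density, so
#'   the reflecting domain boundary does not distort in-view correlations)
#' @param geometry an \code{\link{AcquisitionGeometry}} (pixel size and FOV)
#' @param psfSigma sd of the rendered 2D PSF at the sample plane
#'   (micrometres)
#' @param noise a \code{\link{NoiseModel}}
#' @param marginUm width of the off-view simulation margin (micrometres)
#' @param returnPositions also return the walker trajectory array
#' @return A frames x rows x cols array with attributes
#'   \code{frameInterval} (s) and \code{pixelSize} (um); when
#'   \code{returnPositions} is TRUE, the trajectories are attached as
#'   attribute \code{positions} (frames x walkers x 2, micrometres).
#' @export
simulateDiffusionMovie <- function(spec, geometry, psfSigma = 0.25,
                                   noise = NoiseModel("none", offset = 0),
                                   marginUm = 2, returnPositions = FALSE) {
  stopifnot(validObject(spec))
  nCols <- as.integer(geometry@fov[1]); nRows <- as.integer(geometry@fov[2])
  pi_um <- geometry@pixelSize
  fovX <- nCols * pi_um; fovY <- nRows * pi_um
  if (!is.null(spec@regionMask)) marginUm <- 0 # mask defines the domain
  Lx <- fovX + 2 * marginUm; Ly <- fovY + 2 * marginUm
  dt <- spec@frameInterval
  nT <- as.integer(spec@nFrames)
  nW <- as.integer(round(spec@nWalkers * (Lx * Ly) / (fovX * fovY)))
  stepSd <- sqrt(2 * spec@D * dt)
  sigPx <- psfSigma / pi_um
  mask <- spec@regionMask
  maskOpen <- function(x, y) { # TRUE where walkers may sit
    r <- pmin(pmax(floor(y / pi_um), 0), nRows - 1) + 1
    c <- pmin(pmax(floor(x / pi_um), 0), nCols - 1) + 1
    mask[cbind(r, c)]
  }
  reflect <- function(p, L) { # fold positions back into [0, L]
    p <- abs(p)
    over <- p > L
    p[over] <- 2 * L - p[over]
    pmin(pmax(p, 0), L)
  }
  .withSeed(spec@seed, {
    x <- runif(nW, 0, Lx); y <- runif(nW, 0, Ly)
    if (!is.null(mask)) { # start on open pixels
      for (it in 1:200) {
        bad <- !maskOpen(x, y)
        if (!any(bad)) break
        x[bad] <- runif(sum(bad), 0, Lx); y[bad] <- runif(sum(bad), 0, Ly)
      }
    }
    movie <- array(0, c(nT, nRows, nCols))
    pos <- if (returnPositions) array(NA_real_, c(nT, nW, 2)) else NULL
    for (t in seq_len(nT)) {
      if (t > 1 && stepSd > 0) {
        nx <- reflect(x + rnorm(nW, 0, stepSd), Lx)
        ny <- reflect(y + rnorm(nW, 0, stepSd), Ly)
        if (!is.null(mask)) {
          okm <- maskOpen(nx, ny)
          x[okm] <- nx[okm]; y[okm] <- ny[okm]
        } else {
          x <- nx; y <- ny
        }
      }
      photon <- .renderSpots(nRows, nCols, (y - marginUm) / pi_um,
                             (x - marginUm) / pi_um,
                             rep(sigPx, nW), rep(spec@brightness, nW))
      movie[t, , ] <- addCameraNoise(photon, noise)
      if (returnPositions) {
        pos[t, , 1] <- x - marginUm; pos[t, , 2] <- y - marginUm
      }
    }
    attr(movie, "frameInterval") <- dt
    attr(movie, "pixelSize") <- pi_um
    if (returnPositions) attr(movie, "positions") <- pos
    movie
  })
}

#' Apply a camera noise model to an expected-photon image
#'
#' Shot noise (Poisson), stochastic electron-multiplying gain for EMCCD
#' (Gamma-distributed with mean emGain per photoelectron, which realises the
#' ~sqrt(2) excess noise factor), additive Gaussian read noise, and offset.
#' \code{kind = "none"} returns input + offset exactly. Counts are reported
#' at 1 ADU per electron; for "scmos" the output variance decomposes as
#' mean photons + readNoise^2.
#'
#' @param photonImage nonnegative expected photon counts (matrix or array)
#' @param noise a \code{\link{NoiseModel}}
#' @param seed optional integer seed for reproducible draws
#' @return Count image of the same shape.
#' @export
addCameraNoise <- function(photonImage, noise, seed = NULL) {
  if (any(photonImage < 0)) stop("photon image must be nonnegative")
  if (noise@kind == "none") return(photonImage + noise@offset)
  .withSeed(seed, {
    n <- length(photonImage)
    pe <- rpois(n, lambda = as.vector(photonImage))
    sig <- if (noise@kind == "emccd") {
      out <- numeric(n)
      nz <- pe > 0
      out[nz] <- rgamma(sum(nz), shape = pe[nz], scale = noise@emGain)
      out
    } else as.numeric(pe)
    out <- sig + rnorm(n, 0, noise@readNoise) + noise@offset
    array(out, dim = if (is.null(dim(photonImage))) length(photonImage)
          else dim(photonImage))
  })
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta r)}, converted to micrometres^2/s. Used to
#' set simulator ground truth (e.g. a 9 nm hydrodynamic radius in water at
#' 293 K gives ~24 um^2/s).
#'
#' @param radius hydrodynamic radius (nanometres)
#' @param temperature absolute temperature (kelvin)
#' @param viscosity dynamic viscosity (mPa s; 1.00 for water at 293 K)
#' @return Diffusion coefficient in micrometres^2/s.
#' @examples
#' stokesEinsteinD(9, 293, 1.00) # ~24
#' @export
stokesEinsteinD <- function(radius, temperature = 293, viscosity = 1.00) {
  if (any(viscosity <= 0)) stop("viscosity must be > 0")
  if (any(radius <= 0)) stop("radius must be > 0")
  kB <- 1.380649e-23 # J/K
  d_m2s <- kB * temperature / (6 * pi * viscosity * 1e-3 * radius * 1e-9)
  d_m2s * 1e12
}
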