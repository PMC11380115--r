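#' @import methods
#' @importFrom stats approx coef dnorm fft lm median nextn quantile resid
#'   rnorm rpois runif sd var rgamma
NULL

.posScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

## ---------------------------------------------------------------------------
## Optical design specifications
## ---------------------------------------------------------------------------

#' Gaussian beam specification
#'
#' Parameterizes a stigmatic Gaussian laser beam: vacuum wavelength, 1/e^2
#' waist radius, refractive index of the propagation medium, beam quality
#' factor M^2 and an arbitrary-unit amplitude.
#'
#' @slot wavelength vacuum wavelength (micrometres)
#' @slot waist 1/e^2 intensity waist radius omega_0g (micrometres)
#' @slot refractiveIndex refractive index of the medium (>= 1)
#' @slot beamQualityM2 beam quality factor (>= 1; 1 for an ideal TEM00 beam)
#' @slot amplitude overall intensity scale I0 (arbitrary units, > 0)
#' @export
setClass("GaussianBeamSpec", representation(
  wavelength = "numeric", waist = "numeric", refractiveIndex = "numeric",
  beamQualityM2 = "numeric", amplitude = "numeric"),
  validity = function(object) {
    if (!.posScalar(object@wavelength)) return("wavelength must be a positive scalar (micrometres)")
    if (!.posScalar(object@waist)) return("waist must be a positive scalar (micrometres)")
    if (!.posScalar(object@refractiveIndex) || object@refractiveIndex < 1)
      return("refractiveIndex must be >= 1")
    if (!.posScalar(object@beamQualityM2) || object@beamQualityM2 < 1)
      return("beamQualityM2 must be >= 1")
    if (!.posScalar(object@amplitude)) return("amplitude must be > 0")
    TRUE
  })

#' @param wavelength vacuum wavelength in micrometres
#' @param waist 1/e^2 waist radius in micrometres
#' @param refractiveIndex refractive index of the medium
#' @param beamQualityM2 beam quality factor M^2
#' @param amplitude intensity scale I0 (arbitrary units)
#' @return A \code{GaussianBeamSpec} object.
#' @examples
#' GaussianBeamSpec(wavelength = 0.532, waist = 4)
#' @rdname GaussianBeamSpec-class
#' @export
GaussianBeamSpec <- function(wavelength, waist, refractiveIndex = 1,
                             beamQualityM2 = 1, amplitude = 1) {
  new("GaussianBeamSpec", wavelength = wavelength, waist = waist,
      refractiveIndex = refractiveIndex, beamQualityM2 = beamQualityM2,
      amplitude = amplitude)
}

#' Axicon specification for Bessel-beam generation
#'
#' An axicon of apex angle tau and refractive index n deflects a Gaussian
#' beam into a Bessel-like beam. The axicon parameter alpha0 (the deflection
#' half-angle) is derived as (n - 1) * (pi - tau) / 2, the deflection through
#' the base angle of the cone, unless supplied directly.
#'
#' @slot refractiveIndex axicon glass refractive index
#' @slot apexAngleTau apex angle tau (radians, in (0, pi))
#' @slot alpha0 axicon parameter (radians, > 0)
#' @export
setClass("AxiconSpec", representation(
  refractiveIndex = "numeric", apexAngleTau = "numeric", alpha0 = "numeric"),
  validity = function(object) {
    if (!(object@apexAngleTau > 0 && object@apexAngleTau < pi))
      return("apexAngleTau must lie in (0, pi) radians")
    if (!.posScalar(object@alpha0) || object@alpha0 >= pi / 2)
      return("alpha0 must lie in (0, pi/2)")
    TRUE
  })

#' @param refractiveIndex axicon refractive index
#' @param apexAngleTau apex angle in radians
#' @param alpha0 axicon parameter in radians; derived from the geometry when
#'   omitted
#' @return An \code{AxiconSpec} object.
#' @rdname AxiconSpec-class
#' @export
AxiconSpec <- function(refractiveIndex = 1.45, apexAngleTau = pi - 2 * 0.03 / (refractiveIndex - 1),
                       alpha0 = NULL) {
  if (is.null(alpha0))
    alpha0 <- (refractiveIndex - 1) * (pi - apexAngleTau) / 2
  new("AxiconSpec", refractiveIndex = refractiveIndex,
      apexAngleTau = apexAngleTau, alpha0 = alpha0)
}

#' Airy beam specification
#'
#' Parameters of an exponentially apertured Airy beam produced from a
#' Gaussian beam by a cubic phase: characteristic transverse length x0,
#' apodization factor a, number of phase wraps gamma at the Gaussian waist,
#' and the wave number k = 2 pi / lambda.
#'
#' @slot characteristicLength x0 (micrometres)
#' @slot apodization dimensionless apodization factor a (>= 0)
#' @slot phaseWraps number of phase wraps gamma (> 0)
#' @slot waveNumber k = 2 pi / lambda (1/micrometre)
#' @export
setClass("AirySpec", representation(
  characteristicLength = "numeric", apodization = "numeric",
  phaseWraps = "numeric", waveNumber = "numeric"),
  validity = function(object) {
    if (!.posScalar(object@characteristicLength)) return("characteristicLength must be > 0")
    if (object@apodization < 0) return("apodization must be >= 0")
    if (!.posScalar(object@phaseWraps)) return("phaseWraps must be > 0")
    if (!.posScalar(object@waveNumber)) return("waveNumber must be > 0")
    TRUE
  })

#' @param characteristicLength x0 in micrometres
#' @param apodization apodization factor a
#' @param phaseWraps phase wraps gamma
#' @param wavelength vacuum wavelength in micrometres (sets waveNumber)
#' @return An \code{AirySpec} object.
#' @rdname AirySpec-class
#' @export
AirySpec <- function(characteristicLength, apodization = 0.1, phaseWraps = 5,
                     wavelength = 0.532) {
  new("AirySpec", characteristicLength = characteristicLength,
      apodization = apodization, phaseWraps = phaseWraps,
      waveNumber = 2 * pi / wavelength)
}

#' Lens element of an illumination train
#'
#' One lens in an ordered propagation train. \code{distanceZ} is measured
#' from the focal point of the preceding element. Cylindrical lenses act on
#' a single transverse axis.
#'
#' @slot focalLength focal length (millimetres, nonzero)
#' @slot distanceZ distance from the upstream focus (millimetres, >= 0)
#' @slot axis one of "both", "x_only", "y_only"
#' @export
setClass("LensElement", representation(
  focalLength = "numeric", distanceZ = "numeric", axis = "character"),
  validity = function(object) {
    if (object@focalLength == 0) return("focalLength must be nonzero")
    if (object@distanceZ < 0) return("distanceZ must be >= 0")
    if (!object@axis %in% c("both", "x_only", "y_only"))
      return("axis must be 'both', 'x_only' or 'y_only'")
    TRUE
  })

#' @param focalLength focal length in millimetres
#' @param distanceZ distance from the upstream focus in millimetres
#' @param axis acting axis: "both" (spherical), "x_only" or "y_only"
#'   (cylindrical)
#' @return A \code{LensElement} object.
#' @rdname LensElement-class
#' @export
LensElement <- function(focalLength, distanceZ = 0, axis = "both") {
  new("LensElement", focalLength = focalLength, distanceZ = distanceZ,
      axis = axis)
}

#' Objective lens specification
#'
#' @slot magnification fold magnification (> 0)
#' @slot numericalAperture NA = n sin(theta), 0 < NA <= immersionIndex
#' @slot immersionIndex refractive index of the immersion medium
#' @slot tubeLensFocal tube lens focal length (millimetres)
#' @slot workingDistance working distance (millimetres)
#' @export
setClass("ObjectiveSpec", representation(
  magnification = "numeric", numericalAperture = "numeric",
  immersionIndex = "numeric", tubeLensFocal = "numeric",
  workingDistance = "numeric"),
  validity = function(object) {
    if (!.posScalar(object@magnification)) return("magnification must be > 0")
    if (!.posScalar(object@numericalAperture)) return("numericalAperture must be > 0")
    if (object@numericalAperture > object@immersionIndex)
      return("numericalAperture cannot exceed immersionIndex")
    TRUE
  })

#' @param magnification fold magnification
#' @param numericalAperture numerical aperture
#' @param immersionIndex immersion refractive index
#' @param tubeLensFocal tube lens focal length (mm)
#' @param workingDistance working distance (mm)
#' @return An \code{ObjectiveSpec} object.
#' @examples
#' ObjectiveSpec(40, 0.8, immersionIndex = 1.33)
#' @rdname ObjectiveSpec-class
#' @export
ObjectiveSpec <- function(magnification, numericalAperture,
                          immersionIndex = 1.33, tubeLensFocal = 200,
                          workingDistance = 3.3) {
  new("ObjectiveSpec", magnification = magnification,
      numericalAperture = numericalAperture, immersionIndex = immersionIndex,
      tubeLensFocal = tubeLensFocal, workingDistance = workingDistance)
}

#' Scientific camera specification
#'
#' @slot physicalPixel physical pixel pitch PP (micrometres)
#' @slot readNoise read noise (electrons rms)
#' @slot offset digitizer offset (counts)
#' @slot gainModel "scmos", "emccd" or "none"
#' @slot emGain electron-multiplying gain (fold, >= 1)
#' @slot quantumEfficiency photon-to-electron conversion efficiency in (0, 1]
#' @export
setClass("CameraSpec", representation(
  physicalPixel = "numeric", readNoise = "numeric", offset = "numeric",
  gainModel = "character", emGain = "numeric", quantumEfficiency = "numeric"),
  validity = function(object) {
    if (!.posScalar(object@physicalPixel)) return("physicalPixel must be > 0")
    if (object@readNoise < 0) return("readNoise must be >= 0")
    if (!object@gainModel %in% c("scmos", "emccd", "none"))
      return("gainModel must be 'scmos', 'emccd' or 'none'")
    if (object@quantumEfficiency <= 0 || object@quantumEfficiency > 1)
      return("quantumEfficiency must lie in (0, 1]")
    TRUE
  })

#' @param physicalPixel physical pixel pitch in micrometres
#' @param readNoise read noise in electrons rms
#' @param offset offset in counts
#' @param gainModel "scmos", "emccd" or "none"
#' @param emGain EM gain (fold)
#' @param quantumEfficiency quantum efficiency in (0, 1]
#' @return A \code{CameraSpec} object.
#' @rdname CameraSpec-class
#' @export
CameraSpec <- function(physicalPixel = 6.5, readNoise = 1.6, offset = 100,
                       gainModel = "scmos", emGain = 1,
                       quantumEfficiency = 0.82) {
  new("CameraSpec", physicalPixel = physicalPixel, readNoise = readNoise,
      offset = offset, gainModel = gainModel, emGain = emGain,
      quantumEfficiency = quantumEfficiency)
}

## ---------------------------------------------------------------------------
## Acquisition model
## ---------------------------------------------------------------------------

#' Acquisition geometry of a stage-scanned tilted-sheet microscope
#'
#' The coordinate contract for the whole pipeline. In a tilted-sheet
#' (e.g. iSPIM) geometry the sheet plane makes an angle phi with the sample
#' plane (ideal 45 degrees; 66 degrees measured on the modeled instrument),
#' so z-stage travel produces a lateral image shift of
#' \code{skewPerUm} micrometres per micrometre of travel. When not supplied,
#' the x-skew is derived as tan(90 - phi) and the y-skew is zero.
#'
#' @slot sheetAngle angle between sheet and sample plane (degrees, (0, 90])
#' @slot zStep stage step between z slices (micrometres)
#' @slot pixelSize image pixel size PI (micrometres)
#' @slot fov field of view as c(nCols, nRows) pixels
#' @slot skewPerUm c(sx, sy): lateral shift (micrometres) per micrometre of
#'   stage z travel
#' @export
setClass("AcquisitionGeometry", representation(
  sheetAngle = "numeric", zStep = "numeric", pixelSize = "numeric",
  fov = "numeric", skewPerUm = "numeric"),
  validity = function(object) {
    if (!(object@sheetAngle > 0 && object@sheetAngle <= 90))
      return("sheetAngle must lie in (0, 90] degrees")
    if (!.posScalar(object@zStep)) return("zStep must be > 0")
    if (!.posScalar(object@pixelSize)) return("pixelSize must be > 0")
    if (length(object@fov) != 2L || any(object@fov < 1))
      return("fov must be c(nCols, nRows) with positive entries")
    if (length(object@skewPerUm) != 2L) return("skewPerUm must be c(sx, sy)")
    TRUE
  })

#' @param sheetAngle sheet angle phi in degrees
#' @param zStep z step in micrometres
#' @param pixelSize image pixel size in micrometres
#' @param fov c(nCols, nRows) in pixels
#' @param skewPerUm c(sx, sy) in micrometres of image shift per micrometre of
#'   stage travel; derived from \code{sheetAngle} when NULL
#' @return An \code{AcquisitionGeometry} object.
#' @examples
#' AcquisitionGeometry(sheetAngle = 66, zStep = 5, pixelSize = 0.1625,
#'                     fov = c(64, 64))
#' @rdname AcquisitionGeometry-class
#' @export
AcquisitionGeometry <- function(sheetAngle = 66, zStep = 5,
                                pixelSize = 0.1625, fov = c(64L, 64L),
                                skewPerUm = NULL) {
  if (is.null(skewPerUm))
    skewPerUm <- c(tan((90 - sheetAngle) * pi / 180), 0)
  new("AcquisitionGeometry", sheetAngle = sheetAngle, zStep = zStep,
      pixelSize = pixelSize, fov = as.numeric(fov), skewPerUm = skewPerUm)
}

#' Light-sheet intensity profile at the sample plane
#'
#' \code{thickness} is the full 1/e^2 width of the sheet across its normal,
#' consistent with the Gaussian-waist convention (so the Gaussian axial
#' weight uses omega = thickness / 2); \code{width} is the extent along the
#' sheet.
#'
#' @slot thickness full 1/e^2 width across the sheet normal (micrometres)
#' @slot width sheet width (micrometres)
#' @export
setClass("SheetProfile", representation(
  thickness = "numeric", width = "numeric"),
  validity = function(object) {
    if (!.posScalar(object@thickness)) return("thickness must be > 0")
    if (!.posScalar(object@width)) return("width must be > 0")
    TRUE
  })

#' @param thickness full 1/e^2 thickness in micrometres
#' @param width sheet width in micrometres
#' @return A \code{SheetProfile} object.
#' @rdname SheetProfile-class
#' @export
SheetProfile <- function(thickness = 2.15, width = 7.1) {
  new("SheetProfile", thickness = thickness, width = width)
}

#' Gaussian axial weight of a light sheet
#'
#' Excitation weight exp(-2 d^2 / omega^2) with omega = thickness / 2 at
#' signed distance d from the sheet plane; weight(0) = 1.
#'
#' @param sheet a \code{SheetProfile}
#' @param d signed distance from the sheet plane (micrometres), vectorized
#' @return Numeric weights in (0, 1].
#' @export
sheetAxialWeight <- function(sheet, d) {
  w <- sheet@thickness / 2
  exp(-2 * d^2 / w^2)
}

#' Bead phantom: ground truth for synthetic calibration stacks
#'
#' @slot positions n x 3 matrix of (x, y, z) positions (micrometres)
#' @slot diameters bead diameters (micrometres)
#' @slot brightness expected photons per frame emitted by a bead centred in
#'   the sheet (integrated over its image spot)
#' @slot volumeDims c(X, Y, Z) extents of the phantom volume (micrometres)
#' @export
setClass("BeadPhantom", representation(
  positions = "matrix", diameters = "numeric", brightness = "numeric",
  volumeDims = "numeric"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (n > 0 && ncol(object@positions) != 3L)
      return("positions must be an n x 3 matrix")
    if (length(object@diameters) != n) return("one diameter per bead required")
    if (n > 0 && any(object@diameters <= 0)) return("diameters must be > 0")
    if (length(object@volumeDims) != 3L || any(object@volumeDims <= 0))
      return("volumeDims must be positive c(X, Y, Z)")
    if (n > 0) {
      inb <- object@positions >= 0 &
        object@positions <= matrix(object@volumeDims, n, 3, byrow = TRUE)
      if (!all(inb)) return("bead positions must lie inside volumeDims")
    }
    TRUE
  })

#' @param positions n x 3 matrix of (x, y, z) micrometre positions
#' @param diameters bead diameters (micrometres), recycled to n
#' @param brightness photons per frame for a sheet-centred bead
#' @param volumeDims c(X, Y, Z) extents (micrometres); defaults to the
#'   position bounding box
#' @return A \code{BeadPhantom} object.
#' @rdname BeadPhantom-class
#' @export
BeadPhantom <- function(positions, diameters, brightness = 1e4,
                        volumeDims = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (is.null(volumeDims))
    volumeDims <- apply(positions, 2, function(p) max(p, 0))
  new("BeadPhantom", positions = positions,
      diameters = rep_len(diameters, nrow(positions)),
      brightness = brightness, volumeDims = as.numeric(volumeDims))
}

#' Brownian diffusion movie specification
#'
#' @slot nWalkers number of diffusing emitters
#' @slot D diffusion coefficient (micrometres^2 / s, >= 0)
#' @slot frameInterval frame interval (seconds)
#' @slot nFrames number of frames (>= 2)
#' @slot regionMask optional logical matrix (rows x cols); TRUE marks open
#'   (accessible) pixels of a porous medium
#' @slot brightness expected photons per frame per walker (integrated spot)
#' @slot seed integer random seed
#' @export
setClass("DiffusionSimSpec", representation(
  nWalkers = "numeric", D = "numeric", frameInterval = "numeric",
  nFrames = "numeric", regionMask = "ANY", brightness = "numeric",
  seed = "numeric"),
  validity = function(object) {
    if (object@D < 0) return("D must be >= 0")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    if (object@nFrames < 2) return("nFrames must be >= 2")
    if (!is.null(object@regionMask) && !is.logical(object@regionMask))
      return("regionMask must be NULL or a logical matrix")
    TRUE
  })

#' @param nWalkers number of walkers
#' @param D diffusion coefficient in micrometres^2/s
#' @param frameInterval frame interval in seconds
#' @param nFrames number of frames
#' @param regionMask optional logical porosity mask (rows x cols)
#' @param brightness photons per frame per walker
#' @param seed integer seed
#' @return A \code{DiffusionSimSpec} object.
#' @rdname DiffusionSimSpec-class
#' @export
DiffusionSimSpec <- function(nWalkers = 40, D = 5, frameInterval = 0.002,
                             nFrames = 5000, regionMask = NULL,
                             brightness = 300, seed = 1L) {
  new("DiffusionSimSpec", nWalkers = nWalkers, D = D,
      frameInterval = frameInterval, nFrames = nFrames,
      regionMask = regionMask, brightness = brightness, seed = seed)
}

#' Camera noise model
#'
#' Shot noise is Poisson in all modes except "none". "emccd" applies
#' stochastic electron-multiplying gain (Gamma-distributed, which reproduces
#' the ~sqrt(2) excess noise factor), "scmos" adds Gaussian read noise only,
#' and "none" is a deterministic pass-through plus offset. Counts are
#' reported at unit ADU per electron.
#'
#' @slot kind "none", "scmos" or "emccd"
#' @slot readNoise read noise (electrons rms)
#' @slot offset offset (counts)
#' @slot emGain EM gain (fold, >= 1)
#' @slot excessNoiseFactor EM excess noise factor (~sqrt(2); informational,
#'   the Gamma gain model realises it)
#' @export
setClass("NoiseModel", representation(
  kind = "character", readNoise = "numeric", offset = "numeric",
  emGain = "numeric", excessNoiseFactor = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("none", "scmos", "emccd"))
      return("kind must be 'none', 'scmos' or 'emccd'")
    if (object@readNoise < 0) return("readNoise must be >= 0")
    if (object@emGain < 1) return("emGain must be >= 1")
    TRUE
  })

#' @param kind "none", "scmos" or "emccd"
#' @param readNoise electrons rms
#' @param offset counts
#' @param emGain fold gain (emccd)
#' @param excessNoiseFactor excess noise factor
#' @return A \code{NoiseModel} object.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(kind = "scmos", readNoise = 1.6, offset = 100,
                       emGain = 1, excessNoiseFactor = sqrt(2)) {
  new("NoiseModel", kind = kind, readNoise = readNoise, offset = offset,
      emGain = emGain, excessNoiseFactor = excessNoiseFactor)
}

## ---------------------------------------------------------------------------
## Image containers
## ---------------------------------------------------------------------------

#' Image stack: the unit of exchange between simulator, calibration and
#' reconstruction
#'
#' A 4-dimensional count array ordered slices x frames x rows x cols
#' (frames = 1 for static acquisitions) plus acquisition metadata.
#'
#' @slot data 4D numeric array (slices, frames, rows, cols)
#' @slot meta list with elements \code{pixelSize} (micrometres),
#'   \code{zStep} (micrometres), \code{frameInterval} (seconds) and
#'   optionally \code{skew} (a \code{SkewEstimate})
#' @export
setClass("ImageStack", representation(data = "array", meta = "list"),
  validity = function(object) {
    if (length(dim(object@data)) != 4L)
      return("data must be a 4D array (slices, frames, rows, cols)")
    if (any(dim(object@data) < 1L)) return("all dimensions must be >= 1")
    if (!all(is.finite(object@data) | is.na(object@data)))
      return("counts must be finite (NA marks excluded pixels)")
    m <- object@meta
    for (f in c("pixelSize", "zStep", "frameInterval"))
      if (!is.null(m[[f]]) && m[[f]] <= 0)
        return(paste0("meta$", f, " must be > 0"))
    TRUE
  })

#' @param data 4D array (slices, frames, rows, cols); 3D input (slices, rows,
#'   cols) is promoted to a single-frame stack
#' @param pixelSize image pixel size in micrometres
#' @param zStep z step in micrometres
#' @param frameInterval frame interval in seconds
#' @param skew optional \code{SkewEstimate}
#' @return An \code{ImageStack} object.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(data, pixelSize = 0.1625, zStep = 5,
                       frameInterval = 0.002, skew = NULL) {
  if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(aperm(array(data, c(d, 1L)), c(1, 4, 2, 3)),
                  c(d[1], 1L, d[2], d[3]))
  }
  new("ImageStack", data = data,
      meta = list(pixelSize = pixelSize, zStep = zStep,
                  frameInterval = frameInterval, skew = skew))
}

#' @rdname ImageStack-class
#' @param x an \code{ImageStack}
#' @export
stackData <- function(x) x@data

#' @rdname ImageStack-class
#' @export
stackMeta <- function(x) x@meta

#' Separable 3D Gaussian point spread function
#'
#' @slot lateralFwhm lateral FWHM (pixels)
#' @slot axialFwhm axial FWHM (slices)
#' @slot kernel 3D nonnegative array (rows, cols, slices) of odd dimensions
#'   summing to 1
#' @export
setClass("PSF3D", representation(
  lateralFwhm = "numeric", axialFwhm = "numeric", kernel = "array"),
  validity = function(object) {
    k <- object@kernel
    if (length(dim(k)) != 3L) return("kernel must be 3D")
    if (any(dim(k) %% 2L == 0L)) return("kernel dimensions must be odd")
    if (any(k < 0)) return("kernel must be nonnegative")
    if (abs(sum(k) - 1) > 1e-9) return("kernel must sum to 1 within 1e-9")
    TRUE
  })

#' @rdname PSF3D-class
#' @param x a \code{PSF3D}
#' @export
psfKernel <- function(x) x@kernel

#' Physically scaled voxel volume
#'
#' @slot voxels 3D array (rows, cols, slices); NA marks pixels vacated by
#'   de-skewing
#' @slot scale c(PI, PI, zStep) micrometres per voxel along (row, col, slice)
#' @export
setClass("Volume", representation(voxels = "array", scale = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be 3D")
    if (length(object@scale) != 3L || any(object@scale <= 0))
      return("scale must be positive c(PI, PI, zStep)")
    if (any(object@voxels < 0, na.rm = TRUE))
      return("voxels must be nonnegative")
    TRUE
  })

#' @rdname Volume-class
#' @param x a \code{Volume}
#' @export
voxels <- function(x) x@voxels

#' @rdname Volume-class
#' @export
voxelScale <- function(x) x@scale

## ---------------------------------------------------------------------------
## Calibration results
## ---------------------------------------------------------------------------

#' Pixel-size estimate from bead localizations
#'
#' @slot mean mean image pixel size (micrometres)
#' @slot sd standard deviation over localizations (micrometres)
#' @slot n number of localizations used
#' @export
setClass("PixelSizeEstimate", representation(
  mean = "numeric", sd = "numeric", n = "numeric"),
  validity = function(object) {
    if (object@mean <= 0) return("mean must be > 0")
    if (object@n < 1) return("n must be >= 1")
    TRUE
  })

#' Axial-skew estimate
#'
#' Lateral image shift per micrometre of stage z travel, with the sheet
#' angle implied by the x component.
#'
#' @slot sx x shift (micrometres image / micrometre stage z)
#' @slot sy y shift (micrometres image / micrometre stage z)
#' @slot sheetAngle implied sheet angle (degrees in (0, 90])
#' @slot fitResidual RMS residual of the track fits (micrometres)
#' @export
setClass("SkewEstimate", representation(
  sx = "numeric", sy = "numeric", sheetAngle = "numeric",
  fitResidual = "numeric"),
  validity = function(object) {
    if (!(object@sheetAngle > 0 && object@sheetAngle <= 90))
      return("sheetAngle must lie in (0, 90] degrees")
    TRUE
  })

#' @param sx,sy micrometres of image shift per micrometre of stage z travel
#' @param fitResidual RMS fit residual (micrometres)
#' @return A \code{SkewEstimate}; the sheet angle is derived from \code{sx}.
#' @rdname SkewEstimate-class
#' @export
SkewEstimate <- function(sx, sy = 0, fitResidual = NA_real_) {
  new("SkewEstimate", sx = sx, sy = sy,
      sheetAngle = 90 - atan(max(abs(sx), 0)) * 180 / pi,
      fitResidual = fitResidual)
}

#' Measured sheet dimensions (FWHM at the sample plane)
#'
#' @slot width sheet width FWHM (micrometres)
#' @slot thickness sheet thickness FWHM (micrometres); width >= thickness
#' @export
setClass("SheetDims", representation(width = "numeric", thickness = "numeric"),
  validity = function(object) {
    if (object@thickness <= 0) return("thickness must be > 0")
    if (object@width < object@thickness) return("width must be >= thickness")
    TRUE
  })

## ---------------------------------------------------------------------------
## Dynamics containers
## ---------------------------------------------------------------------------

#' Temporal intensity correlation curve
#'
#' Normalized second-order autocorrelation
#' G(tau) = <dF(t) dF(t+tau)> / <F>^2 evaluated on a pseudo-logarithmic
#' (multi-tau) lag grid.
#'
#' @slot lags lag times (seconds, strictly increasing, >= frame interval)
#' @slot G correlation values
#' @slot samplesPerLag number of products averaged at each lag
#' @slot frameInterval frame interval (seconds)
#' @export
setClass("CorrelationCurve", representation(
  lags = "numeric", G = "numeric", samplesPerLag = "numeric",
  frameInterval = "numeric"),
  validity = function(object) {
    if (length(object@lags) != length(object@G)) return("lags/G length mismatch")
    if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
    if (length(object@lags) && object@lags[1] < object@frameInterval - 1e-12)
      return("first lag must be >= frameInterval")
    if (any(!is.finite(object@G))) return("G must be finite")
    TRUE
  })

#' Fitted FCS diffusion model
#'
#' @slot model "brownian1", "brownian2" or "anomalous"
#' @slot G0 amplitude
#' @slot tauD diffusion time (seconds, > 0)
#' @slot tauD2 second diffusion time ("brownian2" only)
#' @slot fraction fast fraction in [0, 1] ("brownian2" only)
#' @slot alpha anomalous exponent in (0, 2] ("anomalous" only)
#' @slot rss weighted residual sum of squares
#' @slot converged logical convergence flag
#' @export
setClass("FcsFit", representation(
  model = "character", G0 = "numeric", tauD = "numeric", tauD2 = "numeric",
  fraction = "numeric", alpha = "numeric", rss = "numeric",
  converged = "logical"),
  validity = function(object) {
    if (isTRUE(object@converged) && !(is.na(object@tauD) || object@tauD > 0))
      return("tauD must be > 0 for a converged fit")
    if (!is.na(object@fraction) &&
        (object@fraction < 0 || object@fraction > 1))
      return("fraction must lie in [0, 1]")
    if (!is.na(object@alpha) && (object@alpha <= 0 || object@alpha > 2))
      return("alpha must lie in (0, 2]")
    TRUE
  })

#' Per-pixel diffusion map
#'
#' @slot D diffusion coefficients (micrometres^2/s), matrix; NA where invalid
#' @slot validMask logical matrix of valid fits
#' @slot omega focal radius used in D = omega^2 / (4 tauD) (micrometres,
#'   1/e^2 radius of the 2D PSF)
#' @export
setClass("DiffusionMap", representation(
  D = "matrix", validMask = "matrix", omega = "numeric"),
  validity = function(object) {
    if (!all(dim(object@D) == dim(object@validMask)))
      return("D and validMask must have identical dimensions")
    if (any(object@D[object@validMask] <= 0, na.rm = TRUE))
      return("D must be > 0 where valid")
    TRUE
  })

#' Second-order SOFI image
#'
#' @slot values nonnegative correlation values; on the interleaved grid the
#'   array is (2 rows - 1) x (2 cols - 1) with virtual pixels between
#'   physical ones
#' @slot gridKind "native" or "interleaved"
#' @slot clampFraction fraction of pixels whose negative correlation value
#'   was clamped to zero
#' @export
setClass("SofiImage", representation(
  values = "matrix", gridKind = "character", clampFraction = "numeric"),
  validity = function(object) {
    if (!object@gridKind %in% c("native", "interleaved"))
      return("gridKind must be 'native' or 'interleaved'")
    if (any(object@values < 0)) return("values must be nonnegative")
    TRUE
  })

#' Fused fcsSOFI image
#'
#' Hue encodes log10(D) over \code{dRange}; saturation and value encode the
#' normalized SOFI image. Invalid diffusion pixels are rendered unsaturated.
#'
#' @slot rgb rows x cols x 3 array in [0, 1]
#' @slot hue hue channel (NA where the diffusion fit is invalid)
#' @slot saturation saturation channel
#' @slot value value channel
#' @slot dRange c(Dmin, Dmax) of the hue scale (micrometres^2/s)
#' @export
setClass("FusedImage", representation(
  rgb = "array", hue = "matrix", saturation = "matrix", value = "matrix",
  dRange = "numeric"),
  validity = function(object) {
    if (length(dim(object@rgb)) != 3L || dim(object@rgb)[3] != 3L)
      return("rgb must be rows x cols x 3")
    if (any(object@rgb < 0 | object@rgb > 1)) return("rgb must lie in [0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d slice(s) x %d frame(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  m <- object@meta
  cat(sprintf("  pixel %.4g um, z-step %.4g um, frame interval %.4g s\n",
              m$pixelSize, m$zStep, m$frameInterval))
  if (!is.null(m$skew))
    cat(sprintf("  skew: sx=%.3f sy=%.3f um/um (sheet angle %.1f deg)\n",
                m$skew@sx, m$skew@sy, m$skew@sheetAngle))
})

setMethod("show", "BeadPhantom", function(object) {
  cat(sprintf("BeadPhantom: %d bead(s) in %.3g x %.3g x %.3g um volume\n",
              nrow(object@positions), object@volumeDims[1],
              object@volumeDims[2], object@volumeDims[3]))
})

setMethod("show", "SkewEstimate", function(object) {
  cat(sprintf("SkewEstimate: sx=%.4f sy=%.4f um/um; sheet angle %.2f deg; residual %.3g um\n",
              object@sx, object@sy, object@sheetAngle, object@fitResidual))
})

setMethod("show", "PixelSizeEstimate", function(object) {
  cat(sprintf("PixelSizeEstimate: %.4g +/- %.2g um (n = %d)\n",
              object@mean, object@sd, as.integer(object@n)))
})

setMethod("show", "SheetDims", function(object) {
  cat(sprintf("SheetDims: width %.3g um x thickness %.3g um (FWHM)\n",
              object@width, object@thickness))
})

setMethod("show", "FcsFit", function(object) {
  cat(sprintf("FcsFit[%s]: G0=%.4g tauD=%.4g s (converged: %s)\n",
              object@model, object@G0, object@tauD, object@converged))
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume: %d x %d x %d voxels, %.4g x %.4g x %.4g um/voxel\n",
              d[1], d[2], d[3], object@scale[1], object@scale[2],
              object@scale[3]))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags, %.3g-%.3g s, G(first)=%.4g\n",
              length(object@lags), min(object@lags), max(object@lags),
              object@G[1]))
})

setMethod("show", "DiffusionMap", function(object) {
  cat(sprintf("DiffusionMap: %d x %d px, %d valid, median D %.3g um^2/s\n",
              nrow(object@D), ncol(object@D), sum(object@validMask),
              median(object@D[object@validMask], na.rm = TRUE)))
})
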