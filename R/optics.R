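## Closed-form optical design calculators: beam profiles, propagation through
## a lens train, objective resolution, sampling and depth of field.
##
## Unit conventions: lengths in micrometres unless a signature says otherwise;
## objective/camera-level wavelengths are accepted in nanometres and converted
## at the API boundary; angles in radians internally, degrees at the API
## boundary where noted.

#' Gaussian beam intensity profile
#'
#' Transverse/axial intensity of a Gaussian beam,
#' \deqn{I(r, z) = \frac{I_0}{2\pi\omega_{0g}^2(1 + (z/z_{Rg})^2)}
#'   \exp\!\left(\frac{-2 r^2}{\omega_{0g}^2 (1 + (z/z_{Rg})^2)}\right),}
#' with Rayleigh range \eqn{z_{Rg} = \pi \omega_{0g}^2 n / \lambda}. The
#' prefactor is the published closed form; \code{normalize = "peak"} instead
#' scales the on-axis waist intensity to \code{beam@amplitude}, matching the
#' reading of I0 as the beam's maximum intensity. Intensity ratios (e.g. the
#' 1/e^2 waist definition I(waist, 0)/I(0, 0) = exp(-2)) are identical under
#' both conventions.
#'
#' @param beam a \code{\link{GaussianBeamSpec}}
#' @param r radial distance from the beam axis (micrometres), vectorized
#' @param z axial position relative to the waist (micrometres), vectorized
#' @param normalize "printed" (default) or "peak"
#' @return Intensity in arbitrary units.
#' @examples
#' b <- GaussianBeamSpec(0.532, 4)
#' gaussianIntensity(b, r = 4, z = 0) / gaussianIntensity(b, r = 0, z = 0)
#' @export
gaussianIntensity <- function(beam, r, z, normalize = c("printed", "peak")) {
  normalize <- match.arg(normalize)
  .assertFinite(r, "r"); .assertFinite(z, "z")
  zR <- pi * beam@waist^2 * beam@refractiveIndex / beam@wavelength
  spread <- 1 + (z / zR)^2
  core <- exp(-2 * r^2 / (beam@waist^2 * spread))
  if (normalize == "printed")
    beam@amplitude / (2 * pi * beam@waist^2 * spread) * core
  else
    beam@amplitude / spread * core
}

#' Gaussian beam propagation parameters
#'
#' Rayleigh range \eqn{z_{Rg} = \pi \omega_{0g}^2 n / \lambda}, confocal
#' parameter \eqn{b_g = 2 z_{Rg}}, and the spreading function
#' \eqn{\omega(z) = \omega_{0g}\sqrt{1 + (z/z_{Rg})^2}}.
#'
#' @param beam a \code{\link{GaussianBeamSpec}}
#' @return A list with \code{rayleighRange} (um), \code{confocalParameter}
#'   (um) and \code{radiusAt(z)}, a function of axial position (um).
#' @examples
#' gaussianPropagation(GaussianBeamSpec(0.532, 4))$confocalParameter # ~189 um
#' @export
gaussianPropagation <- function(beam) {
  zR <- pi * beam@waist^2 * beam@refractiveIndex / beam@wavelength
  w0 <- beam@waist
  list(rayleighRange = zR,
       confocalParameter = 2 * zR,
       radiusAt = function(z) w0 * sqrt(1 + (z / zR)^2))
}

#' Beam waist from the far-field divergence angle
#'
#' \eqn{\omega_{0g} = \lambda / (\pi \theta)} (far-field approximation,
#' no higher-order correction terms).
#'
#' @param wavelength vacuum wavelength (micrometres)
#' @param divergence far-field half-angle divergence theta (radians, > 0)
#' @return Waist radius in micrometres.
#' @export
waistFromDivergence <- function(wavelength, divergence) {
  if (any(divergence <= 0)) stop("divergence must be > 0")
  wavelength / (pi * divergence)
}

#' Bessel beam intensity profile from an axicon
#'
#' \deqn{I(r, z) = 4 I_0 k \sin(\alpha_0)\, \omega_{0g} \frac{z}{b_b}
#'   \exp(-2 z^2 / b_b^2)\, J_0^2(k r \sin \alpha_0),}
#' with \eqn{k = 2\pi/\lambda} and the Bessel confocal parameter
#' \eqn{b_b = \omega_{0g} \cos\alpha_0 / \sin\alpha_0}.
#'
#' @param inputWaist waist of the incident Gaussian beam (micrometres)
#' @param axicon an \code{\link{AxiconSpec}}
#' @param wavelength vacuum wavelength (micrometres)
#' @param r radial coordinate (micrometres), vectorized
#' @param z longitudinal coordinate (micrometres), vectorized
#' @param amplitude intensity scale I0
#' @return Intensity in arbitrary units.
#' @export
besselProfile <- function(inputWaist, axicon, wavelength, r, z,
                          amplitude = 1) {
  .assertFinite(r, "r"); .assertFinite(z, "z")
  a0 <- axicon@alpha0
  k <- 2 * pi / wavelength
  bb <- besselConfocal(inputWaist, a0)
  4 * amplitude * k * sin(a0) * inputWaist * (z / bb) *
    exp(-2 * z^2 / bb^2) * besselJ(k * r * sin(a0), 0)^2
}

#' Bessel-beam confocal parameter
#'
#' \eqn{b_b = \omega_{0g} \cos\alpha_0 / \sin\alpha_0}: the propagation range
#' over which the concentric-ring structure holds its intensity.
#'
#' @param inputWaist incident Gaussian waist (micrometres)
#' @param alpha0 axicon parameter (radians, in (0, pi/2))
#' @return Confocal parameter in micrometres.
#' @examples
#' besselConfocal(6, 0.03) # ~200 um
#' @export
besselConfocal <- function(inputWaist, alpha0) {
  if (any(alpha0 <= 0 | alpha0 >= pi / 2))
    stop("alpha0 must lie in (0, pi/2); alpha0 = 0 gives a divergent range")
  inputWaist * cos(alpha0) / sin(alpha0)
}

#' Airy function Ai of a complex argument
#'
#' Entire-function Maclaurin series
#' \eqn{Ai(z) = c_1 f(z) - c_2 g(z)} with
#' \eqn{c_1 = 3^{-2/3}/\Gamma(2/3)}, \eqn{c_2 = 3^{-1/3}/\Gamma(1/3)}.
#' Accurate in double precision for moderate |z| (roughly |z| < 9, the
#' regime of beam-profile evaluation near the main lobe); cancellation grows
#' beyond that.
#'
#' @param z real or complex argument, vectorized
#' @return Ai(z), complex when z is complex.
#' @export
airyAi <- function(z) {
  c1 <- 3^(-2 / 3) / gamma(2 / 3)
  c2 <- 3^(-1 / 3) / gamma(1 / 3)
  out <- vapply(z, function(zz) {
    z3 <- zz^3
    f <- ftrm <- 1 + 0i
    g <- gtrm <- zz + 0i
    for (k in 0:120) {
      ftrm <- ftrm * z3 / ((3 * k + 2) * (3 * k + 3))
      gtrm <- gtrm * z3 / ((3 * k + 3) * (3 * k + 4))
      f <- f + ftrm
      g <- g + gtrm
      if (Mod(ftrm) < 1e-18 * (Mod(f) + 1e-300) &&
          Mod(gtrm) < 1e-18 * (Mod(g) + 1e-300)) break
    }
    c1 * f - c2 * g
  }, complex(1))
  if (is.numeric(z) && all(Im(out) == 0)) Re(out) else out
}

#' Airy beam intensity profile
#'
#' Intensity of an exponentially apertured Airy beam,
#' \deqn{I(x, y, z) = e^{2a(x/x_0 - z^2/(2k^2x_0^4))}
#'   e^{2a(y/x_0 - z^2/(2k^2x_0^4))}
#'   \left|\mathrm{Ai}(u_x)\,\mathrm{Ai}(u_y)\right|^2,}
#' with \eqn{u_x = x/x_0 - z^2/(4k^2x_0^4) + i a z/(k x_0^2)} (and likewise
#' for y). The form is symmetric in x and y; at \code{apodization = 0} and
#' \code{z = 0} it reduces to \eqn{Ai^2(x/x_0) Ai^2(y/x_0)}.
#'
#' @param spec an \code{\link{AirySpec}}
#' @param x,y transverse coordinates (micrometres), vectorized together
#' @param z propagation coordinate (micrometres)
#' @return Intensity in arbitrary units.
#' @export
airyProfile <- function(spec, x, y, z = 0) {
  .assertFinite(x, "x"); .assertFinite(y, "y"); .assertFinite(z, "z")
  x0 <- spec@characteristicLength
  a <- spec@apodization
  k <- spec@waveNumber
  zz <- z / (k * x0^2)
  ux <- x / x0 - z^2 / (4 * k^2 * x0^4) + 1i * a * zz
  uy <- y / x0 - z^2 / (4 * k^2 * x0^4) + 1i * a * zz
  env <- exp(2 * a * (x / x0 - z^2 / (2 * k^2 * x0^4))) *
    exp(2 * a * (y / x0 - z^2 / (2 * k^2 * x0^4)))
  env * Mod(airyAi(ux) * airyAi(uy))^2
}

#' Airy-beam propagation length
#'
#' FWHM-based propagation length of the Airy main lobe,
#' \eqn{b_{Ai} = \tfrac12 \sqrt{2\ln 2}\; 2\pi n \omega_{0g}^2 / (\gamma
#' \lambda)}. The published rendering of this expression is typographically
#' ambiguous, so the grouping is isolated behind the \code{grouping}
#' argument: supply \code{function(waist, phaseWraps, refractiveIndex,
#' wavelength)} to swap in a corrected form.
#'
#' @param inputWaist Gaussian waist at the cubic phase element (micrometres)
#' @param phaseWraps number of phase wraps gamma at the waist
#' @param refractiveIndex medium refractive index
#' @param wavelength vacuum wavelength (micrometres)
#' @param grouping optional replacement grouping function
#' @return Propagation length in micrometres.
#' @export
airyPropagation <- function(inputWaist, phaseWraps, refractiveIndex = 1,
                            wavelength = 0.532, grouping = NULL) {
  if (is.null(grouping))
    grouping <- function(w0, g, n, lam)
      0.5 * sqrt(2 * log(2)) * 2 * pi * n * w0^2 / (g * lam)
  grouping(inputWaist, phaseWraps, refractiveIndex, wavelength)
}

#' Propagate a Gaussian beam through an ordered lens train
#'
#' Applies the focused-diameter relation \eqn{2\omega_z = 4 f \lambda M^2 /
#' (\pi\, \omega(z))} at each element, where \eqn{\omega(z)} is the beam
#' radius arriving at the element from the upstream focus (spreading
#' function of the upstream waist). Spherical elements act on both
#' transverse axes; cylindrical elements (\code{x_only}/\code{y_only})
#' update only their acting axis, leaving the other bitwise unchanged. The
#' final orthogonal beam diameters are the sheet width (larger) and
#' thickness (smaller).
#'
#' @param beam input \code{\link{GaussianBeamSpec}} (waist at the first
#'   element's upstream focus)
#' @param elements list of \code{\link{LensElement}}, ordered along the path
#' @return A list with \code{perElement} (data.frame of per-axis waist radii
#'   in micrometres after each element), \code{finalDiameters} c(x, y) (um),
#'   \code{sheetWidth} and \code{sheetThickness} (um).
#' @export
propagateTrain <- function(beam, elements) {
  lam <- beam@wavelength
  m2 <- beam@beamQualityM2
  n <- beam@refractiveIndex
  waist <- c(x = beam@waist, y = beam@waist)
  rows <- vector("list", length(elements))
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    f_um <- el@focalLength * 1e3
    z_um <- el@distanceZ * 1e3
    for (ax in c("x", "y")) {
      if ((el@axis == "x_only" && ax == "y") ||
          (el@axis == "y_only" && ax == "x")) next
      zR <- pi * waist[[ax]]^2 * n / lam
      wz <- waist[[ax]] * sqrt(1 + (z_um / zR)^2)
      if (wz == 0) stop("beam radius at element is zero")
      waist[[ax]] <- abs(2 * f_um * lam * m2 / (pi * wz))
    }
    rows[[i]] <- data.frame(element = i, axis_x_waist_um = waist[["x"]],
                            axis_y_waist_um = waist[["y"]])
  }
  dia <- 2 * waist
  list(perElement = do.call(rbind, rows),
       finalDiameters = c(x = unname(dia["x"]), y = unname(dia["y"])),
       sheetWidth = max(dia), sheetThickness = min(dia))
}

#' Objective focal length, resolution and diffraction limit
#'
#' \eqn{f_{obj} = f_{tl}/M}; lateral resolution \eqn{R_{x,y} = \lambda/(2
#' NA)}; axial resolution \eqn{R_z = 2\lambda/NA^2}; diffraction limit
#' \eqn{d = \lambda/(2 NA)}.
#'
#' @param objective an \code{\link{ObjectiveSpec}}
#' @param emissionWavelength emission wavelength in nanometres
#' @return A list with \code{fobj} (mm), \code{lateral} (nm), \code{axial}
#'   (nm) and \code{diffractionLimit} (nm).
#' @examples
#' objectiveResolution(ObjectiveSpec(100, 1.5, immersionIndex = 1.52), 532)
#' @export
objectiveResolution <- function(objective, emissionWavelength) {
  na <- objective@numericalAperture
  if (na <= 0) stop("numerical aperture must be > 0")
  list(fobj = objective@tubeLensFocal / objective@magnification,
       lateral = emissionWavelength / (2 * na),
       axial = 2 * emissionWavelength / na^2,
       diffractionLimit = emissionWavelength / (2 * na))
}

#' System PSF of a two-objective light-sheet microscope
#'
#' The system PSF is the elementwise product of the illumination and
#' detection PSFs. When both inputs are unit-sum and \code{renormalize} is
#' TRUE, the product is rescaled to unit sum.
#'
#' @param psfIllumination,psfDetection nonnegative 3D arrays of identical
#'   shape
#' @param renormalize rescale the product to unit sum (default TRUE)
#' @return 3D array of the same shape.
#' @export
lsmPsf <- function(psfIllumination, psfDetection, renormalize = TRUE) {
  if (!identical(dim(psfIllumination), dim(psfDetection)))
    stop("illumination and detection PSFs must have identical shapes")
  if (any(psfIllumination < 0) || any(psfDetection < 0))
    stop("PSFs must be nonnegative")
  out <- psfIllumination * psfDetection
  if (renormalize && sum(out) > 0) out <- out / sum(out)
  out
}

#' Image pixel size and required magnification
#'
#' \eqn{P_I = P_P / M}: the camera's physical pixel pitch divided by the
#' objective magnification gives the image (sample-plane) pixel size.
#' Supplying \code{targetPixelSize} instead returns the magnification
#' required to reach it.
#'
#' @param physicalPixel camera pixel pitch PP (micrometres), or a
#'   \code{\link{CameraSpec}}
#' @param magnification objective magnification (fold)
#' @param targetPixelSize desired image pixel size (micrometres)
#' @return A list with \code{imagePixel} (um) or
#'   \code{requiredMagnification} (fold).
#' @examples
#' pixelGeometry(6.5, magnification = 40)$imagePixel          # 0.1625 um
#' pixelGeometry(13, targetPixelSize = 0.1)$requiredMagnification # 130
#' @export
pixelGeometry <- function(physicalPixel, magnification = NULL,
                          targetPixelSize = NULL) {
  if (is(physicalPixel, "CameraSpec"))
    physicalPixel <- physicalPixel@physicalPixel
  if (physicalPixel <= 0) stop("physicalPixel must be > 0")
  if (!is.null(magnification)) {
    if (magnification <= 0) stop("magnification must be > 0")
    list(imagePixel = physicalPixel / magnification)
  } else if (!is.null(targetPixelSize)) {
    if (targetPixelSize <= 0) stop("targetPixelSize must be > 0")
    list(requiredMagnification = physicalPixel / targetPixelSize)
  } else stop("supply magnification or targetPixelSize")
}

#' Expected bead image extent in pixels
#'
#' The number of pixels a bead of known diameter should span at a given
#' image pixel size: diameter / PI.
#'
#' @param beadDiameter bead diameter (micrometres)
#' @param imagePixel image pixel size PI (micrometres)
#' @return Expected extent in pixels.
#' @examples
#' expectedBeadPsfPx(2.10, 0.163) # ~12.9 px
#' @export
expectedBeadPsfPx <- function(beadDiameter, imagePixel) {
  if (any(imagePixel <= 0)) stop("imagePixel must be > 0")
  beadDiameter / imagePixel
}

#' Depth of field of the detection objective
#'
#' \eqn{DOF = \lambda n / NA^2 + n P_I / (M\, NA)}: wave-optical term plus
#' the pixel-sampling (geometric) term.
#'
#' @param emissionWavelength emission wavelength (nanometres)
#' @param immersionIndex refractive index n of the immersion medium
#' @param numericalAperture detection NA
#' @param imagePixel image pixel size PI (micrometres)
#' @param magnification objective magnification (fold)
#' @return DOF in micrometres.
#' @examples
#' depthOfField(575, 1.33, 0.8, 0.1625, 40) # ~1.20 um
#' @export
depthOfField <- function(emissionWavelength, immersionIndex,
                         numericalAperture, imagePixel, magnification) {
  if (numericalAperture <= 0) stop("numericalAperture must be > 0")
  lam_um <- emissionWavelength / 1e3
  lam_um * immersionIndex / numericalAperture^2 +
    immersionIndex * imagePixel / (magnification * numericalAperture)
}
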