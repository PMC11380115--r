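## Static reconstruction pipeline: de-skew -> 3D Richardson-Lucy
## deconvolution -> local background thresholding -> volume assembly ->
## line-section analysis. Pipeline order follows the acquisition-correction
## sequence: import/ROI, de-skew, deconvolve, threshold, assemble.

#' De-skew a stage-scanned stack
#'
#' Slice k (0-based) is translated by (-k zStep sx / PI, -k zStep sy / PI)
#' pixels relative to slice 0, undoing the parallelogram geometry of
#' tilted-sheet stage scanning. Sub-pixel shifts use bilinear interpolation
#' (integer shifts degenerate to exact translation); vacated margins are
#' filled with NA, which downstream statistics exclude.
#'
#' @param stack an \code{\link{ImageStack}}
#' @param skew a \code{\link{SkewEstimate}}; defaults to the stack's
#'   metadata skew
#' @return The de-skewed \code{\link{ImageStack}} (metadata skew recorded).
#' @export
deskew <- function(stack, skew = NULL) {
  if (is.null(skew)) skew <- stack@meta$skew
  if (is.null(skew)) stop("no skew estimate available")
  d <- dim(stack@data)
  pi_um <- stack@meta$pixelSize
  zstep <- stack@meta$zStep
  maxShift <- (d[1] - 1) * zstep / pi_um * max(abs(c(skew@sx, skew@sy)))
  if (maxShift >= max(d[3], d[4]))
    stop("skew shift exceeds the frame size")
  out <- stack@data
  for (k in seq_len(d[1]) - 1L) {
    dCol <- -k * zstep * skew@sx / pi_um
    dRow <- -k * zstep * skew@sy / pi_um
    if (dCol == 0 && dRow == 0) next
    for (f in seq_len(d[2]))
      out[k + 1L, f, , ] <- .translateBilinear(out[k + 1L, f, , ],
                                               dRow, dCol)
  }
  stack@data <- out
  stack@meta$skew <- skew
  stack
}

#' Build a separable 3D Gaussian PSF
#'
#' @param lateralFwhm lateral FWHM (pixels, > 0)
#' @param axialFwhm axial FWHM (slices, > 0)
#' @param dims odd kernel dimensions c(rows, cols, slices); default covers
#'   +/- 2.5 FWHM
#' @return A \code{\link{PSF3D}} with a unit-sum kernel.
#' @export
buildPsf3d <- function(lateralFwhm, axialFwhm, dims = NULL) {
  if (lateralFwhm <= 0 || axialFwhm <= 0) stop("FWHMs must be > 0")
  if (is.null(dims)) {
    lat <- 2L * ceiling(1.25 * lateralFwhm) + 1L
    ax <- 2L * ceiling(1.25 * axialFwhm) + 1L
    dims <- c(lat, lat, ax)
  }
  if (any(dims %% 2L == 0L)) stop("kernel dimensions must be odd")
  g1 <- function(n, fwhm) {
    s <- fwhmToSigma(fwhm)
    x <- seq_len(n) - (n + 1) / 2
    dnorm(x, 0, s)
  }
  k <- outer(outer(g1(dims[1], lateralFwhm), g1(dims[2], lateralFwhm)),
             g1(dims[3], axialFwhm))
  k <- array(k, dims)
  new("PSF3D", lateralFwhm = lateralFwhm, axialFwhm = axialFwhm,
      kernel = k / sum(k))
}

# circular 3D convolution of a padded array with a kernel embedded at the
# origin; conj = TRUE applies the adjoint (correlation)
.fftConv3 <- function(xf, hf, dims, conj = FALSE) {
  hf <- if (conj) Conj(hf) else hf
  Re(fft(xf * hf, inverse = TRUE)) / prod(dims)
}

# reflective padding of a 3D array by h = c(hr, hc, hs) on each side
.padReflect3 <- function(x, h) {
  idx <- function(n, hh) {
    if (hh == 0) return(seq_len(n))
    c(rev(seq_len(min(hh, n))), seq_len(n),
      n + 1 - rev(seq_len(min(hh, n))))
  }
  x[idx(dim(x)[1], h[1]), idx(dim(x)[2], h[2]), idx(dim(x)[3], h[3]),
    drop = FALSE]
}

#' Richardson-Lucy 3D deconvolution
#'
#' Iterative maximum-likelihood deconvolution with multiplicative,
#' nonnegativity-preserving updates, run in the frequency domain with
#' reflective boundary padding. Iteration stops after
#' \code{nIterations} or when the mean relative update falls below
#' \code{epsilon}.
#'
#' @param volume nonnegative 3D array (rows, cols, slices) or
#'   \code{\link{Volume}}
#' @param psf a \code{\link{PSF3D}}
#' @param nIterations maximum iterations (default 20)
#' @param epsilon relative-change stopping threshold (default 1e-4)
#' @return Deconvolved object of the same type; attribute
#'   \code{iterationResiduals} records the per-iteration relative change.
#' @export
deconvolveRL <- function(volume, psf, nIterations = 20L, epsilon = 1e-4) {
  isVol <- is(volume, "Volume")
  x <- if (isVol) volume@voxels else volume
  if (length(dim(x)) != 3L) stop("volume must be a 3D array")
  nas <- is.na(x)
  x[nas] <- 0
  if (any(x < 0)) stop("volume must be nonnegative")
  if (all(x == 0)) {
    warning("all-zero volume returned unchanged")
    return(volume)
  }
  k <- psf@kernel
  h <- (dim(k) - 1L) %/% 2L
  xp <- .padReflect3(x, h)
  dims <- dim(xp)
  # embed the kernel with its centre at the origin (circular convolution)
  kp <- array(0, dims)
  kp[seq_len(dim(k)[1]), seq_len(dim(k)[2]), seq_len(dim(k)[3])] <- k
  for (j in 1:3) {
    perm <- seq_len(dim(kp)[j])
    shift <- c(perm[(h[j] + 1):length(perm)], perm[seq_len(h[j])])
    kp <- switch(j, kp[shift, , , drop = FALSE],
                 kp[, shift, , drop = FALSE], kp[, , shift, drop = FALSE])
  }
  hf <- fft(kp)
  est <- xp
  epsDiv <- 1e-12 * max(xp)
  residuals <- numeric(0)
  for (it in seq_len(nIterations)) {
    blur <- pmax(.fftConv3(fft(est), hf, dims), 0)
    ratio <- xp / (blur + epsDiv)
    upd <- pmax(.fftConv3(fft(ratio), hf, dims, conj = TRUE), 0)
    newEst <- est * upd
    rel <- sum(abs(newEst - est)) / (sum(est) + epsDiv)
    residuals <- c(residuals, rel)
    est <- newEst
    if (rel < epsilon) break
  }
  out <- est[h[1] + seq_len(dim(x)[1]), h[2] + seq_len(dim(x)[2]),
             h[3] + seq_len(dim(x)[3]), drop = FALSE]
  out[nas] <- NA
  attr(out, "iterationResiduals") <- residuals
  if (isVol) {
    volume@voxels <- array(out, dim(x))
    attr(volume@voxels, "iterationResiduals") <- residuals
    volume
  } else out
}

# threshold map for one frame: per-tile mean + 3 sd at tile centres,
# bilinearly interpolated between centres (clamped beyond the outer centres)
.thresholdMap <- function(frame, tileSize) {
  nr <- nrow(frame); nc <- ncol(frame)
  rBreaks <- unique(c(seq(1, nr, by = tileSize), nr + 1))
  cBreaks <- unique(c(seq(1, nc, by = tileSize), nc + 1))
  nTr <- length(rBreaks) - 1L; nTc <- length(cBreaks) - 1L
  stat <- matrix(0, nTr, nTc)
  rCen <- numeric(nTr); cCen <- numeric(nTc)
  for (i in seq_len(nTr)) rCen[i] <- mean(rBreaks[i]:(rBreaks[i + 1] - 1))
  for (j in seq_len(nTc)) cCen[j] <- mean(cBreaks[j]:(cBreaks[j + 1] - 1))
  for (i in seq_len(nTr)) for (j in seq_len(nTc)) {
    tile <- frame[rBreaks[i]:(rBreaks[i + 1] - 1),
                  cBreaks[j]:(cBreaks[j + 1] - 1)]
    tile <- tile[is.finite(tile)]
    m <- if (length(tile)) mean(tile) else 0
    s <- if (length(tile) > 1) sd(tile) else 0
    stat[i, j] <- m + 3 * s
  }
  # separable bilinear interpolation from tile centres to pixel centres
  interpAxis <- function(cen, vals, xout) {
    if (length(cen) == 1L) return(matrix(vals, length(xout), ncol(vals)))
    apply(vals, 2, function(v)
      approx(cen, v, xout = xout, rule = 2)$y)
  }
  rowsInterp <- interpAxis(rCen, stat, seq_len(nr))           # nr x nTc
  t(interpAxis(cCen, t(rowsInterp), seq_len(nc)))             # nr x nc
}

#' Local mean + 3 sigma background thresholding
#'
#' A threshold map is built from per-tile background statistics (mean plus
#' three standard deviations, computed on raw tile counts with NA-marked
#' pixels excluded), bilinearly interpolated between tile centres, and
#' subtracted: output = max(0, frame - map). For an \code{ImageStack} the
#' correction is applied to every frame of every slice. NA pixels (de-skew
#' margins) stay NA.
#'
#' @param x a 2D count matrix or an \code{\link{ImageStack}}
#' @param tileSize tile edge length in pixels (>= 4, at most the frame size)
#' @return Object of the same type with the background removed.
#' @export
thresholdBackground <- function(x, tileSize = 16L) {
  if (tileSize < 4L) stop("tileSize must be >= 4")
  one <- function(frame) {
    if (tileSize > nrow(frame) || tileSize > ncol(frame))
      stop("tileSize exceeds the frame dimensions")
    map <- .thresholdMap(frame, tileSize)
    out <- frame - map
    out[out < 0] <- 0
    out[!is.finite(frame)] <- NA
    out
  }
  if (is(x, "ImageStack")) {
    d <- dim(x@data)
    for (k in seq_len(d[1])) for (f in seq_len(d[2]))
      x@data[k, f, , ] <- one(x@data[k, f, , ])
    x
  } else one(x)
}

#' Assemble a physically scaled volume from a static stack
#'
#' Reorders a single-frame-per-slice stack (or pre-fused dynamics images)
#' into a (rows, cols, slices) voxel grid with physical scale
#' (PI, PI, zStep) micrometres per voxel. Voxel values equal the input
#' counts bit-exactly; no resampling is performed.
#'
#' @param stack an \code{\link{ImageStack}} with one frame per slice
#' @return A \code{\link{Volume}}.
#' @export
assembleVolume <- function(stack) {
  d <- dim(stack@data)
  if (d[2] != 1L)
    stop("assembleVolume expects one frame per slice (fuse dynamics movies first)")
  m <- stack@meta
  if (is.null(m$pixelSize) || is.null(m$zStep))
    stop("pixelSize and zStep metadata are required")
  vox <- array(aperm(stack@data[, 1, , , drop = FALSE], c(3, 4, 1, 2)),
               c(d[3], d[4], d[1]))
  new("Volume", voxels = vox,
      scale = c(m$pixelSize, m$pixelSize, m$zStep))
}

#' Intensity line section with FWHM
#'
#' Samples the intensity along a straight segment (bilinear within a frame,
#' trilinear through a volume) and reports the FWHM of the largest peak in
#' physical units. When no peak exceeds half of (max - baseline) the FWHM is
#' flagged undefined (NA).
#'
#' @param x a 2D matrix or a \code{\link{Volume}}
#' @param p0,p1 segment endpoints; c(x, y) in 0-based pixel coordinates for
#'   a matrix, c(x, y, z) in voxel coordinates for a volume
#' @param nSamples number of samples along the segment
#' @param pixelSize micrometres per pixel (matrix input only; volumes carry
#'   their own scale)
#' @return A list with \code{distance} (micrometres along the segment),
#'   \code{profile}, \code{fwhm} (micrometres or NA) and
#'   \code{fwhmDefined}.
#' @export
lineSection <- function(x, p0, p1, nSamples = 100L, pixelSize = 1) {
  if (all(p0 == p1)) stop("zero-length segment")
  tt <- seq(0, 1, length.out = nSamples)
  if (is(x, "Volume")) {
    sc <- x@scale
    xs <- p0[1] + tt * (p1[1] - p0[1])
    ys <- p0[2] + tt * (p1[2] - p0[2])
    zs <- p0[3] + tt * (p1[3] - p0[3])
    nz <- dim(x@voxels)[3]
    z0 <- pmin(pmax(floor(zs), 0), nz - 1)
    z1 <- pmin(z0 + 1, nz - 1)
    fz <- zs - z0
    lower <- vapply(seq_along(tt), function(i)
      .bilinearSample(x@voxels[, , z0[i] + 1], ys[i], xs[i]), numeric(1))
    upper <- vapply(seq_along(tt), function(i)
      .bilinearSample(x@voxels[, , z1[i] + 1], ys[i], xs[i]), numeric(1))
    prof <- lower * (1 - fz) + upper * fz
    seg <- c((p1[1] - p0[1]) * sc[2], (p1[2] - p0[2]) * sc[1],
             (p1[3] - p0[3]) * sc[3])
  } else {
    xs <- p0[1] + tt * (p1[1] - p0[1])
    ys <- p0[2] + tt * (p1[2] - p0[2])
    prof <- .bilinearSample(x, ys, xs)
    seg <- c((p1[1] - p0[1]) * pixelSize, (p1[2] - p0[2]) * pixelSize)
  }
  dist <- tt * sqrt(sum(seg^2))
  fwhm <- .profileFwhm(dist, prof)
  list(distance = dist, profile = prof, fwhm = fwhm,
       fwhmDefined = is.finite(fwhm))
}
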