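## Calibration procedures: sub-pixel bead localization, pixel-size
## estimation from bead images, axial-skew quantification from a z-series,
## sheet-angle trigonometry, and sheet-dimension measurement by FWHM.

#' Localize fluorescent beads in a frame
#'
#' Local maxima above a count threshold are refined by least-squares fits of
#' a symmetric 2D Gaussian plus constant background within a square window.
#' Fits that fail to converge, leave the window, or return a non-positive
#' width are dropped; the number dropped is reported as an attribute.
#'
#' @param frame 2D count matrix
#' @param detectionThreshold minimum raw count for a candidate local maximum
#'   (include any camera offset)
#' @param window odd fit-window edge length in pixels
#' @return A data.frame with one row per localization: \code{x}, \code{y}
#'   (sub-pixel, 0-based pixel-centre coordinates; x = column, y = row),
#'   \code{sigma} and \code{fwhm} (pixels, fwhm = 2 sqrt(2 ln 2) sigma),
#'   \code{amplitude}, \code{background} (counts). Attribute
#'   \code{nDropped} counts discarded fits.
#' @export
localizeBeads <- function(frame, detectionThreshold, window = 9L) {
  if (length(dim(frame)) != 2L) stop("frame must be a 2D matrix")
  if (window %% 2L == 0L) stop("window must be odd")
  half <- (window - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  f0 <- frame
  f0[!is.finite(f0)] <- -Inf
  # local maxima over the full fit window (non-maximum suppression), away
  # from the border
  cand <- which(
    f0 > detectionThreshold &
      row(f0) > half & row(f0) <= nr - half &
      col(f0) > half & col(f0) <= nc - half)
  isMax <- vapply(cand, function(i) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    v <- f0[r, c]
    nb <- f0[(r - half):(r + half), (c - half):(c + half)]
    v >= max(nb) && sum(nb == v) == 1L
  }, logical(1))
  cand <- cand[isMax]
  res <- list(); dropped <- 0L
  for (i in cand) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    win <- frame[(r - half):(r + half), (c - half):(c + half)]
    if (any(!is.finite(win))) { dropped <- dropped + 1L; next }
    # moment-based start values
    bg0 <- min(win)
    w0 <- pmax(win - bg0, 0)
    cen <- .centroid(w0)
    tot <- sum(w0)
    sig0 <- sqrt(max(0.25, (sum(w0 * (row(w0) - 1 - cen["row"])^2) +
                              sum(w0 * (col(w0) - 1 - cen["col"])^2)) /
                       (2 * tot)))
    rr <- as.vector(row(win)) - 1; cc <- as.vector(col(win)) - 1
    zz <- as.vector(win)
    resid <- function(p) {
      zz - (p[5] + p[4] * exp(-((rr - p[1])^2 + (cc - p[2])^2) /
                                (2 * p[3]^2)))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(cen[["row"]], cen[["col"]], sig0, max(w0), bg0),
        fn = resid,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info < 1 || fit$info > 4) {
      dropped <- dropped + 1L; next
    }
    p <- fit$par
    inWin <- p[1] >= 0 && p[1] <= window - 1 && p[2] >= 0 &&
      p[2] <= window - 1
    if (!inWin || p[3] <= 0 || p[4] <= 0) { dropped <- dropped + 1L; next }
    res[[length(res) + 1L]] <- data.frame(
      x = c - 1 - half + p[2], y = r - 1 - half + p[1],
      sigma = p[3], fwhm = sigmaToFwhm(p[3]),
      amplitude = p[4], background = p[5])
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
               fwhm = numeric(0), amplitude = numeric(0),
               background = numeric(0))
  attr(out, "nDropped") <- dropped
  out
}

#' Estimate the image pixel size from bead images
#'
#' Each localization's fitted spot extent (FWHM, pixels) of a bead of known
#' physical diameter gives one pixel-size sample PI_i = diameter / fwhm_i;
#' the estimate is their mean and sd.
#'
#' @param beadDiameter known bead diameter (micrometres)
#' @param fwhms fitted spot FWHMs (pixels), one per localization
#' @return A \code{\link{PixelSizeEstimate}}.
#' @examples
#' estimatePixelSize(2.10, rep(11.67, 5))
#' @export
estimatePixelSize <- function(beadDiameter, fwhms) {
  if (!length(fwhms)) stop("at least one FWHM is required")
  if (any(fwhms <= 0)) stop("FWHMs must be > 0")
  pis <- beadDiameter / fwhms
  new("PixelSizeEstimate", mean = mean(pis),
      sd = if (length(pis) > 1) sd(pis) else 0, n = length(pis))
}

# nearest-neighbour linking of per-slice localizations into tracks with a
# per-slice gate (px); beads lost between slices terminate their track
.linkTracks <- function(locs, gate = 3) {
  tracks <- list()
  active <- integer(0) # track index by last position
  lastXY <- matrix(numeric(0), 0, 2)
  for (k in seq_along(locs)) {
    L <- locs[[k]]
    assigned <- rep(FALSE, nrow(L))
    newLast <- matrix(NA_real_, 0, 2); newActive <- integer(0)
    if (length(active) && nrow(L)) {
      for (j in seq_along(active)) {
        d <- sqrt((L$x - lastXY[j, 1])^2 + (L$y - lastXY[j, 2])^2)
        d[assigned] <- Inf
        m <- which.min(d)
        if (length(m) && is.finite(d[m]) && d[m] <= gate) {
          ti <- active[j]
          tracks[[ti]] <- rbind(tracks[[ti]],
                                data.frame(slice = k, x = L$x[m], y = L$y[m]))
          assigned[m] <- TRUE
          newActive <- c(newActive, ti)
          newLast <- rbind(newLast, c(L$x[m], L$y[m]))
        }
      }
    }
    if (nrow(L)) for (m in which(!assigned)) {
      tracks[[length(tracks) + 1L]] <-
        data.frame(slice = k, x = L$x[m], y = L$y[m])
      newActive <- c(newActive, length(tracks))
      newLast <- rbind(newLast, c(L$x[m], L$y[m]))
    }
    active <- newActive; lastXY <- newLast
  }
  tracks
}

#' Measure axial skew from a bead z-series
#'
#' Beads imaged at known stage z positions are localized per slice, linked
#' across slices by nearest-neighbour tracking (gate 3 px per slice), and
#' each track's centroid displacement (micrometres, via the pixel size) is
#' regressed against stage z travel. The slopes give (sx, sy); the sheet
#' angle follows from \code{\link{sheetAngleFromShift}} applied to the
#' per-step x shift. Untrackable beads (fewer than 3 slices) are excluded
#' and counted.
#'
#' @param stack an \code{\link{ImageStack}} of bead images at successive
#'   stage positions (frame 1 of each slice is used)
#' @param detectionThreshold localization threshold (counts)
#' @param window localization window (odd, pixels)
#' @param gate linking gate (pixels per slice); the default admits the
#'   worst-case shift of a 45-degree sheet, zStep / pixelSize, plus 3 px of
#'   localization slack
#' @return A \code{\link{SkewEstimate}}; attribute \code{nExcluded} counts
#'   dropped tracks, \code{nTracks} the tracks used.
#' @export
measureAxialSkew <- function(stack, detectionThreshold, window = 9L,
                             gate = NULL) {
  d <- dim(stack@data)
  if (d[1] < 3L) stop("at least 3 z positions are required")
  pi_um <- stack@meta$pixelSize
  zstep <- stack@meta$zStep
  if (is.null(gate)) gate <- zstep / pi_um + 3
  locs <- lapply(seq_len(d[1]), function(k)
    localizeBeads(stack@data[k, 1, , ], detectionThreshold, window))
  tracks <- .linkTracks(locs, gate)
  ok <- vapply(tracks, nrow, 0L) >= 3L
  excluded <- sum(!ok)
  tracks <- tracks[ok]
  if (!length(tracks)) stop("no bead trackable across >= 3 slices")
  slopes <- vapply(tracks, function(tr) {
    z <- (tr$slice - tr$slice[1]) * zstep
    fx <- lm(I(tr$x * pi_um) ~ z)
    fy <- lm(I(tr$y * pi_um) ~ z)
    c(coef(fx)[2], coef(fy)[2],
      sqrt(mean(c(resid(fx), resid(fy))^2)))
  }, numeric(3))
  est <- SkewEstimate(sx = mean(slopes[1, ]), sy = mean(slopes[2, ]),
                      fitResidual = sqrt(mean(slopes[3, ]^2)))
  attr(est, "nExcluded") <- excluded
  attr(est, "nTracks") <- length(tracks)
  est
}

#' Sheet angle from the apparent lateral shift per z step
#'
#' In a tilted-sheet geometry the apparent in-image shift per stage z step
#' encodes the sheet angle: \eqn{\phi = 90^\circ - \arctan(\Delta x /
#' \Delta z)}. A shift equal to the step gives the ideal 45 degrees; zero
#' shift means the sheet is orthogonal to the stage axis (90 degrees).
#'
#' @param apparentShift observed lateral image shift per z step
#'   (micrometres, >= 0)
#' @param zStep stage z step (micrometres, > 0)
#' @return Sheet angle in degrees.
#' @examples
#' sheetAngleFromShift(2.2, 5) # ~66 degrees
#' @export
sheetAngleFromShift <- function(apparentShift, zStep) {
  if (any(zStep <= 0)) stop("zStep must be > 0")
  if (any(apparentShift < 0)) stop("apparentShift must be >= 0")
  90 - atan(apparentShift / zStep) * 180 / pi
}

#' Measure sheet dimensions from a beam-profiler image
#'
#' The beam spot's principal axes are found from its intensity second
#' moments; 1D profiles through the centroid along each principal axis give
#' the FWHMs, converted to sample-plane micrometres by the profiler pixel
#' pitch and the (de)magnification between profiler and sample plane.
#'
#' @param profileImage 2D intensity image of the beam cross-section
#' @param pixelPitch profiler pixel pitch (micrometres)
#' @param demagnification fold demagnification from profiler plane to sample
#'   plane (1 returns camera-plane dimensions)
#' @param saturationLevel counts at or above which the profile is flagged as
#'   saturated (attribute \code{saturated})
#' @return A \code{\link{SheetDims}} (width >= thickness, FWHM in
#'   micrometres at the sample plane).
#' @export
sheetDimsFromProfile <- function(profileImage, pixelPitch,
                                 demagnification = 1,
                                 saturationLevel = Inf) {
  img <- profileImage
  img[!is.finite(img)] <- 0
  saturated <- any(profileImage >= saturationLevel, na.rm = TRUE)
  w <- pmax(img - min(img), 0)
  cen <- .centroid(w)
  rr <- row(w) - 1 - cen["row"]; cc <- col(w) - 1 - cen["col"]
  tot <- sum(w)
  cov <- matrix(c(sum(w * rr^2), sum(w * rr * cc),
                  sum(w * rr * cc), sum(w * cc^2)) / tot, 2, 2)
  ev <- eigen(cov, symmetric = TRUE)
  fwhms <- vapply(1:2, function(j) {
    v <- ev$vectors[, j] # (row, col) direction
    tmax <- max(nrow(img), ncol(img))
    tt <- seq(-tmax, tmax, by = 0.25)
    prof <- .bilinearSample(img, cen["row"] + tt * v[1],
                            cen["col"] + tt * v[2])
    .profileFwhm(tt, prof)
  }, numeric(1))
  dims <- sort(fwhms * pixelPitch / demagnification, decreasing = TRUE)
  out <- new("SheetDims", width = dims[1], thickness = dims[2])
  attr(out, "saturated") <- saturated
  out
}
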