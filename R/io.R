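## TIFF stack I/O with JSON metadata sidecars.
##
## On disk a stack is a multi-page 16-bit unsigned TIFF, pages ordered
## slice-major (all frames of slice 1, then slice 2, ...), plus a sidecar
## "<path>.json" recording dimensions and acquisition metadata
## {PI_um, z_step_um, frame_interval_s, skew:{sx, sy, phi_deg}}.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF
#'
#' Counts must be integers in [0, 65535]; a write followed by
#' \code{\link{readStack}} round-trips bit-exactly. NA pixels (de-skew
#' margins) are stored as 0 and their presence noted in the sidecar.
#'
#' @param stack an \code{\link{ImageStack}}
#' @param path output TIFF path; the sidecar goes to \code{paste0(path,
#'   ".json")}
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  d <- dim(stack@data)
  x <- stack@data
  hadNA <- any(is.na(x))
  x[is.na(x)] <- 0
  if (any(x < 0 | x > 65535) || any(x != round(x)))
    stop("counts must be integers in [0, 65535] for 16-bit TIFF output")
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (k in seq_len(d[1])) for (f in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- matrix(x[k, f, , ], d[3], d[4]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  m <- stack@meta
  side <- list(slices = d[1], frames = d[2], rows = d[3], cols = d[4],
               PI_um = m$pixelSize, z_step_um = m$zStep,
               frame_interval_s = m$frameInterval,
               na_as_zero = hadNA)
  if (!is.null(m$skew))
    side$skew <- list(sx = m$skew@sx, sy = m$skew@sy,
                      phi_deg = m$skew@sheetAngle)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF files
#'
#' A single path with a JSON sidecar restores the written stack (dimensions
#' and metadata from the sidecar). Multiple paths are imported as one slice
#' per file in path-sorted ascending z order, each file contributing its
#' pages as frames. Mixed bit depths or mismatched frame shapes are
#' rejected.
#'
#' @param paths one or more TIFF paths
#' @param frameRange optional c(first, last) frames to keep (1-based,
#'   inclusive)
#' @param roi optional region of interest, list(rows = c(first, last),
#'   cols = c(first, last)), 1-based inclusive bounds
#' @param pixelSize,zStep,frameInterval metadata used when no sidecar is
#'   present
#' @return An \code{\link{ImageStack}}.
#' @export
readStack <- function(paths, frameRange = NULL, roi = NULL,
                      pixelSize = 0.1625, zStep = 5, frameInterval = 0.002) {
  if (!all(file.exists(paths))) stop("missing input file(s)")
  skew <- NULL
  if (length(paths) == 1L && file.exists(.sidecarPath(paths))) {
    side <- jsonlite::read_json(.sidecarPath(paths), simplifyVector = TRUE)
    pages <- tiff::readTIFF(paths, all = TRUE, as.is = TRUE)
    dims <- vapply(pages, dim, numeric(2))
    if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1)
      stop("mismatched frame shapes")
    data <- array(0, c(side$slices, side$frames, side$rows, side$cols))
    i <- 0L
    for (k in seq_len(side$slices)) for (f in seq_len(side$frames)) {
      i <- i + 1L
      data[k, f, , ] <- pages[[i]]
    }
    pixelSize <- side$PI_um; zStep <- side$z_step_um
    frameInterval <- side$frame_interval_s
    if (!is.null(side$skew))
      skew <- SkewEstimate(sx = side$skew$sx, sy = side$skew$sy)
  } else {
    paths <- sort(paths)
    perFile <- lapply(paths, tiff::readTIFF, all = TRUE, as.is = TRUE)
    allPages <- unlist(perFile, recursive = FALSE)
    dims <- vapply(allPages, dim, numeric(2))
    if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1)
      stop("mismatched frame shapes")
    if (length(unique(vapply(allPages, storage.mode, ""))) > 1)
      stop("mixed data types across files")
    nFrames <- vapply(perFile, length, 0L)
    if (length(unique(nFrames)) > 1)
      stop("all files must contain the same number of frames")
    data <- array(0, c(length(paths), nFrames[1],
                       dims[1, 1], dims[2, 1]))
    for (k in seq_along(perFile)) for (f in seq_len(nFrames[1]))
      data[k, f, , ] <- perFile[[k]][[f]]
  }
  if (!is.null(frameRange))
    data <- data[, frameRange[1]:frameRange[2], , , drop = FALSE]
  if (!is.null(roi)) {
    d <- dim(data)
    if (any(roi$rows < 1) || roi$rows[2] > d[3] ||
        any(roi$cols < 1) || roi$cols[2] > d[4])
      stop("roi out of bounds")
    data <- data[, , roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2],
                 drop = FALSE]
  }
  ImageStack(data, pixelSize = pixelSize, zStep = zStep,
             frameInterval = frameInterval, skew = skew)
}
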