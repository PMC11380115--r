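# shared numeric helpers

# 2*sqrt(2*log(2)): FWHM of a Gaussian of unit sd
.FWHM_SD <- 2 * sqrt(2 * log(2))

#' Convert between Gaussian FWHM and standard deviation
#'
#' @param fwhm full width at half maximum
#' @param sigma standard deviation
#' @return The corresponding sd (resp. FWHM), same units as the input.
#' @export
fwhmToSigma <- function(fwhm) fwhm / .FWHM_SD

#' @rdname fwhmToSigma
#' @export
sigmaToFwhm <- function(sigma) sigma * .FWHM_SD

# evaluate expr with a local RNG state seeded by `seed` (NULL = leave RNG
# alone); never touches the caller's stream when seeded
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.assertFinite <- function(x, name) {
  if (!all(is.finite(x)))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  invisible(x)
}

# bilinear sample of matrix `img` at fractional 0-based (row, col) positions;
# returns NA outside the array or where any contributing pixel is NA
.bilinearSample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  # clamp the upper neighbour for points exactly on the last row/col
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  ok <- r0 >= 0 & c0 >= 0 & r0 <= nr - 1 & c0 <= nc - 1
  out <- rep(NA_real_, length(row))
  if (any(ok)) {
    i00 <- r0[ok] + 1 + (c0[ok]) * nr
    i10 <- r1[ok] + 1 + (c0[ok]) * nr
    i01 <- r0[ok] + 1 + (c1[ok]) * nr
    i11 <- r1[ok] + 1 + (c1[ok]) * nr
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i11] * fr[ok] * fc[ok]
  }
  out
}

# translate matrix by (dRow, dCol) pixels (content moves by +dRow/+dCol);
# vacated margins become NA; integer shifts degenerate to exact translation
.translateBilinear <- function(img, dRow, dCol) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- (seq_len(nr) - 1) - dRow
  cols <- (seq_len(nc) - 1) - dCol
  grid <- expand.grid(row = rows, col = cols)
  matrix(.bilinearSample(img, grid$row, grid$col), nr, nc)
}

# FWHM of the largest peak of a sampled 1D profile by linear interpolation of
# the half-maximum crossings; baseline = profile minimum. Returns NA when no
# peak rises above half of (max - baseline).
.profileFwhm <- function(x, y) {
  ok <- is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  base <- min(y)
  pk <- which.max(y)
  half <- base + (y[pk] - base) / 2
  if (y[pk] <= base) return(NA_real_)
  # walk left
  i <- pk
  while (i > 1 && y[i] > half) i <- i - 1
  if (y[i] > half) return(NA_real_)
  xl <- x[i] + (x[i + 1] - x[i]) * (half - y[i]) / (y[i + 1] - y[i])
  j <- pk
  while (j < length(y) && y[j] > half) j <- j + 1
  if (y[j] > half) return(NA_real_)
  xr <- x[j - 1] + (x[j] - x[j - 1]) * (half - y[j - 1]) / (y[j] - y[j - 1])
  xr - xl
}

# intensity-weighted centroid (0-based row/col) of a matrix
.centroid <- function(img) {
  img[!is.finite(img)] <- 0
  tot <- sum(img)
  rows <- (seq_len(nrow(img)) - 1)
  cols <- (seq_len(ncol(img)) - 1)
  c(row = sum(rowSums(img) * rows) / tot,
    col = sum(colSums(img) * cols) / tot)
}
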