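## fcsSOFI engine: pixel-wise temporal autocorrelation on a multi-tau lag
## grid, FCS diffusion-model fitting, diffusion maps via D = omega^2/(4 tauD),
## second-order cross-correlation SOFI images, and hue/saturation fusion.

# pseudo-logarithmic (multi-tau) lag grid in frames: dense up to `base`,
# then doubling spacing per octave
.multitauLags <- function(maxLag, base = 16L) {
  lags <- seq_len(min(base, maxLag))
  step <- 2L
  top <- base
  while (top < maxLag) {
    nxt <- seq(top + step, min(maxLag, top * 2L), by = step)
    lags <- c(lags, nxt)
    top <- top * 2L
    step <- step * 2L
  }
  unique(lags[lags <= maxLag])
}

# exact normalized autocorrelation G(tau) = <dF(t) dF(t+tau)>/<F>^2 at the
# requested integer lags, via FFT (zero-padded, so identical to the direct
# O(N^2) estimator up to roundoff)
.acf_exact <- function(series, lags) {
  n <- length(series)
  mu <- mean(series)
  dF <- series - mu
  np <- nextn(2L * n, 2L)
  pad <- c(dF, rep(0, np - n))
  ac <- Re(fft(fft(pad) * Conj(fft(pad)), inverse = TRUE))[seq_len(n)] / np
  # ac[k+1] = sum_t dF(t) dF(t+k); normalize per-lag by the sample count
  ac[lags + 1] / ((n - lags) * mu^2)
}

#' Pixel intensity autocorrelation curve
#'
#' Second-order normalized autocorrelation
#' \eqn{G(\tau) = \langle \delta F(t)\,\delta F(t+\tau)\rangle / \langle F
#' \rangle^2} with \eqn{\delta F = F - \langle F\rangle}, evaluated on a
#' multi-tau (pseudo-logarithmic) lag grid. Values are computed with the
#' exact FFT estimator at every lag (no octave binning), so they agree with
#' a direct O(N^2) correlator to machine precision.
#'
#' @param series intensity counts over time (length >= 64)
#' @param frameInterval frame interval (seconds)
#' @param lagScheme "multitau", "linear", or an integer vector of lags in
#'   frames
#' @param maxLag largest lag in frames (default length/4)
#' @return A \code{\link{CorrelationCurve}}.
#' @export
autocorrelate <- function(series, frameInterval, lagScheme = "multitau",
                          maxLag = NULL) {
  n <- length(series)
  if (n < 64L) stop("series must have at least 64 samples")
  if (mean(series) == 0) stop("zero-mean series cannot be normalized")
  if (is.null(maxLag)) maxLag <- n %/% 4L
  maxLag <- min(maxLag, n - 2L)
  lags <- if (is.numeric(lagScheme)) {
    sort(unique(as.integer(lagScheme)))
  } else if (identical(lagScheme, "linear")) {
    seq_len(maxLag)
  } else .multitauLags(maxLag)
  if (any(lags < 1L)) stop("lags must be >= 1 frame")
  G <- .acf_exact(series, lags)
  new("CorrelationCurve", lags = lags * frameInterval, G = G,
      samplesPerLag = n - lags, frameInterval = frameInterval)
}

# model functions G(tau; p)
.fcsModelFun <- function(model) {
  switch(model,
    brownian1 = function(p, tau) p[1] / (1 + tau / p[2]),
    brownian2 = function(p, tau)
      p[1] * (p[3] / (1 + tau / p[2]) + (1 - p[3]) / (1 + tau / p[4])),
    anomalous = function(p, tau) p[1] / (1 + (tau / p[2])^p[3]))
}

#' Fit an FCS diffusion model to a correlation curve
#'
#' Weighted nonlinear least squares (weights sqrt(samples per lag)) of a
#' 2D diffusion model: \code{brownian1} \eqn{G_0/(1+\tau/\tau_D)};
#' \code{brownian2} \eqn{G_0[f/(1+\tau/\tau_{D1}) +
#' (1-f)/(1+\tau/\tau_{D2})]}; \code{anomalous}
#' \eqn{G_0/(1+(\tau/\tau_D)^\alpha)}. Initial values come from curve
#' heuristics (G0 from the first lag, tauD from the half-amplitude lag);
#' tauD is bounded by the frame interval and the curve duration.
#' Non-convergence is reported honestly via the \code{converged} flag with
#' parameters set NA.
#'
#' @param curve a \code{\link{CorrelationCurve}}
#' @param model "brownian1", "brownian2" or "anomalous"
#' @param init optional named list of start values (G0, tauD, tauD2,
#'   fraction, alpha)
#' @param fixedAlpha optional fixed anomalous exponent (fit G0, tauD only)
#' @param baseline also fit an additive baseline G_inf (nuisance term that
#'   absorbs the negative offset a finite-series mean-subtracted
#'   correlation estimator acquires; recommended for series shorter than
#'   ~100 correlation times)
#' @return An \code{\link{FcsFit}}; the fitted baseline, if any, is
#'   attached as attribute \code{baseline}.
#' @export
fitFcs <- function(curve, model = c("brownian1", "brownian2", "anomalous"),
                   init = NULL, fixedAlpha = NULL, baseline = FALSE) {
  model <- match.arg(model)
  tau <- curve@lags
  G <- curve@G
  w <- sqrt(curve@samplesPerLag)
  failFit <- function() new("FcsFit", model = model, G0 = NA_real_,
                            tauD = NA_real_, tauD2 = NA_real_,
                            fraction = NA_real_, alpha = NA_real_,
                            rss = NA_real_, converged = FALSE)
  G0i <- if (!is.null(init$G0)) init$G0 else G[1]
  if (!is.finite(G0i) || G0i <= 0) return(failFit())
  tauDi <- if (!is.null(init$tauD)) init$tauD else {
    below <- which(G < G0i / 2)
    if (length(below)) tau[below[1]] else tau[length(tau)] / 2
  }
  lo_tau <- curve@frameInterval
  hi_tau <- max(tau) * 10
  tauDi <- min(max(tauDi, lo_tau), hi_tau)
  fn <- .fcsModelFun(model)
  setup <- switch(model,
    brownian1 = list(par = c(G0i, tauDi),
                     lower = c(0, lo_tau), upper = c(Inf, hi_tau)),
    brownian2 = list(par = c(G0i, max(tauDi / 5, lo_tau), 0.5,
                             min(tauDi * 5, hi_tau)),
                     lower = c(0, lo_tau, 0, lo_tau),
                     upper = c(Inf, hi_tau, 1, hi_tau)),
    anomalous = if (is.null(fixedAlpha))
      list(par = c(G0i, tauDi, 1),
           lower = c(0, lo_tau, 0.1), upper = c(Inf, hi_tau, 2))
    else list(par = c(G0i, tauDi), lower = c(0, lo_tau),
              upper = c(Inf, hi_tau)))
  if (baseline) { # additive G_inf nuisance parameter, initialized at 0
    setup$par <- c(setup$par, 0)
    setup$lower <- c(setup$lower, -Inf)
    setup$upper <- c(setup$upper, Inf)
  }
  nb <- length(setup$par)
  resid <- if (model == "anomalous" && !is.null(fixedAlpha))
    function(p) {
      off <- if (baseline) p[nb] else 0
      core <- if (baseline) p[-nb] else p
      w * (G - off - .fcsModelFun("anomalous")(c(core, fixedAlpha), tau))
    }
  else function(p) {
    off <- if (baseline) p[nb] else 0
    core <- if (baseline) p[-nb] else p
    w * (G - off - fn(core, tau))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = setup$par, fn = resid, lower = setup$lower,
                       upper = setup$upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(failFit())
  p <- fit$par
  bval <- if (baseline) p[length(p)] else 0
  if (baseline) p <- p[-length(p)]
  rss <- sum(fit$fvec^2)
  out <- switch(model,
    brownian1 = new("FcsFit", model = model, G0 = p[1], tauD = p[2],
                    tauD2 = NA_real_, fraction = NA_real_,
                    alpha = NA_real_, rss = rss, converged = TRUE),
    brownian2 = {
      # order components so tauD is the dominant-fraction one
      if (p[3] < 0.5) p <- c(p[1], p[4], 1 - p[3], p[2])
      new("FcsFit", model = model, G0 = p[1], tauD = p[2],
          tauD2 = p[4], fraction = p[3], alpha = NA_real_,
          rss = rss, converged = TRUE)
    },
    anomalous = new("FcsFit", model = model, G0 = p[1], tauD = p[2],
                    tauD2 = NA_real_, fraction = NA_real_,
                    alpha = if (is.null(fixedAlpha)) p[3] else fixedAlpha,
                    rss = rss, converged = TRUE))
  attr(out, "baseline") <- bval
  out
}

#' Diffusion map from per-pixel diffusion times
#'
#' \eqn{D = \omega^2 / (4 \tau_D)} per valid pixel, where \eqn{\omega} is
#' the focal radius of the 2D PSF. The documented convention for
#' \eqn{\omega} is the 1/e^2 radius of the Gaussian PSF intensity profile
#' (i.e. 2 sigma = FWHM / 1.1774); with this convention the pipeline
#' recovers the ground-truth D of a simulated Brownian movie. Pixels with
#' invalid fits or non-positive tauD are masked, never propagated.
#'
#' @param tauD matrix of per-pixel diffusion times (seconds; NA = invalid),
#'   or a list of \code{\link{FcsFit}} with a \code{dim} attribute
#' @param omega focal radius (micrometres, 1/e^2 PSF radius)
#' @param validMask optional logical matrix further restricting validity
#' @return A \code{\link{DiffusionMap}}.
#' @examples
#' diffusionMap(matrix(0.005, 2, 2), omega = 0.3) # D = 4.5 um^2/s
#' @export
diffusionMap <- function(tauD, omega, validMask = NULL) {
  if (omega <= 0) stop("omega must be > 0")
  if (is.list(tauD)) {
    dims <- dim(tauD)
    td <- vapply(tauD, function(f)
      if (isTRUE(f@converged)) f@tauD else NA_real_, numeric(1))
    tauD <- matrix(td, dims[1], dims[2])
  }
  valid <- is.finite(tauD) & tauD > 0
  if (!is.null(validMask)) valid <- valid & validMask
  D <- matrix(NA_real_, nrow(tauD), ncol(tauD))
  D[valid] <- omega^2 / (4 * tauD[valid])
  new("DiffusionMap", D = D, validMask = valid, omega = omega)
}

#' Second-order cross-correlation SOFI image
#'
#' Per-pixel zero-mean fluctuations \eqn{\delta F} are correlated at the
#' given frame lag. On the native grid each pixel carries its
#' autocorrelation \eqn{AC(\tau)}. On the interleaved (2x densified) grid,
#' virtual pixels at the midpoints of horizontal and vertical neighbour
#' pairs carry the symmetrized cross-correlation
#' \eqn{XC(r_1, r_2, \tau) = \langle \delta F(r_1, t)\,\delta F(r_2,
#' t+\tau)\rangle} (diagonal midpoints use the mean of the two diagonal
#' pairs). Cross-correlation between distinct pixels rejects the common
#' (aliased) noise floor of single-pixel variance. Negative values are
#' clamped to zero and the clamped fraction recorded.
#'
#' @param movie frames x rows x cols array (>= 2 frames)
#' @param lag correlation lag in frames (>= 1, < number of frames)
#' @param gridKind "interleaved" (default) or "native"
#' @return A \code{\link{SofiImage}}.
#' @export
sofiXc2 <- function(movie, lag = 1L, gridKind = c("interleaved", "native")) {
  gridKind <- match.arg(gridKind)
  d <- dim(movie)
  if (length(d) != 3L || d[1] < 2L) stop("movie must be frames x rows x cols")
  if (lag < 1L || lag >= d[1]) stop("lag must satisfy 1 <= lag < n_frames")
  nT <- d[1]; nR <- d[2]; nC <- d[3]
  mu <- colMeans(movie)                    # rows x cols
  dF <- sweep(movie, c(2, 3), mu)
  a <- dF[seq_len(nT - lag), , , drop = FALSE]
  b <- dF[lag + seq_len(nT - lag), , , drop = FALSE]
  xcorr <- function(shiftR, shiftC) {
    ra <- seq_len(nR - shiftR); ca <- seq_len(nC - shiftC)
    rb <- ra + shiftR; cb <- ca + shiftC
    (colMeans(a[, ra, ca, drop = FALSE] * b[, rb, cb, drop = FALSE]) +
       colMeans(a[, rb, cb, drop = FALSE] * b[, ra, ca, drop = FALSE])) / 2
  }
  ac <- colMeans(a * b)
  if (gridKind == "native") {
    neg <- sum(ac < 0)
    ac[ac < 0] <- 0
    return(new("SofiImage", values = ac, gridKind = "native",
               clampFraction = neg / length(ac)))
  }
  out <- matrix(0, 2 * nR - 1, 2 * nC - 1)
  out[seq(1, 2 * nR - 1, 2), seq(1, 2 * nC - 1, 2)] <- ac
  out[seq(2, 2 * nR - 2, 2), seq(1, 2 * nC - 1, 2)] <- xcorr(1, 0)
  out[seq(1, 2 * nR - 1, 2), seq(2, 2 * nC - 2, 2)] <- xcorr(0, 1)
  diag1 <- xcorr(1, 1)                                  # (r,c)-(r+1,c+1)
  # anti-diagonal: shift rows down, cols up
  ra <- seq_len(nR - 1); ca <- seq_len(nC - 1)
  diag2 <- (colMeans(a[, ra + 1, ca, drop = FALSE] *
                       b[, ra, ca + 1, drop = FALSE]) +
              colMeans(a[, ra, ca + 1, drop = FALSE] *
                         b[, ra + 1, ca, drop = FALSE])) / 2
  out[seq(2, 2 * nR - 2, 2), seq(2, 2 * nC - 2, 2)] <- (diag1 + diag2) / 2
  neg <- sum(out < 0)
  out[out < 0] <- 0
  new("SofiImage", values = out, gridKind = "interleaved",
      clampFraction = neg / length(out))
}

# bilinear upsampling of a native-grid matrix onto the interleaved
# (2n-1) grid
.upsampleInterleaved <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- seq(0, nr - 1, by = 0.5)
  cols <- seq(0, nc - 1, by = 0.5)
  grid <- expand.grid(row = rows, col = cols)
  matrix(.bilinearSample(m, grid$row, grid$col),
         length(rows), length(cols))
}

#' Fuse SOFI structure with FCS dynamics
#'
#' Builds the fcsSOFI representation: hue encodes log10(D) clipped to
#' \code{dRange} (affine map from \code{hueStart} to \code{hueEnd});
#' saturation marks pixels with a valid diffusion fit; value is the SOFI
#' image normalized to its 99.5th percentile. A native-grid diffusion map is
#' bilinearly upsampled when the SOFI image is interleaved.
#'
#' @param sofi a \code{\link{SofiImage}}
#' @param dmap a \code{\link{DiffusionMap}} on the native grid
#' @param dRange c(Dmin, Dmax) of the hue scale (micrometres^2/s)
#' @param colormap list with \code{hueStart}, \code{hueEnd} in [0, 1]
#'   (default blue -> red)
#' @return A \code{\link{FusedImage}}.
#' @export
fuseImages <- function(sofi, dmap, dRange = c(0.1, 100),
                       colormap = list(hueStart = 2 / 3, hueEnd = 0)) {
  D <- dmap@D
  valid <- dmap@validMask
  if (!any(valid)) stop("no valid diffusion pixels to fuse")
  if (sofi@gridKind == "interleaved" &&
      !all(dim(sofi@values) == dim(D))) {
    Dv <- D; Dv[!valid] <- NA
    D <- .upsampleInterleaved(Dv)
    valid <- is.finite(D)
  }
  if (!all(dim(sofi@values) == dim(D)))
    stop("SOFI image and diffusion map grids are not aligned")
  lo <- log10(dRange[1]); hi <- log10(dRange[2])
  frac <- (pmin(pmax(log10(D), lo), hi) - lo) / (hi - lo)
  hue <- colormap$hueStart + frac * (colormap$hueEnd - colormap$hueStart)
  hue[!valid] <- NA
  ref <- quantile(sofi@values, 0.995, na.rm = TRUE)
  val <- if (ref > 0) pmin(sofi@values / ref, 1) else sofi@values * 0
  sat <- matrix(1, nrow(val), ncol(val))
  sat[!valid] <- 0
  h <- ifelse(is.na(hue), 0, hue)
  rgbv <- grDevices::col2rgb(grDevices::hsv(pmin(pmax(h, 0), 1), sat,
                                            val)) / 255
  rgbArr <- array(0, c(nrow(val), ncol(val), 3))
  for (ch in 1:3) rgbArr[, , ch] <- matrix(rgbv[ch, ], nrow(val), ncol(val))
  new("FusedImage", rgb = rgbArr, hue = hue, saturation = sat, value = val,
      dRange = dRange)
}

#' Collapse a per-slice movie to one fcsSOFI image
#'
#' The full dynamics chain for one z slice: per-pixel autocorrelation,
#' FCS model fit and diffusion map (Eq. D = omega^2 / 4 tauD), plus the
#' cross-correlation SOFI image, fused into a single hue/saturation image
#' consumable by \code{\link{assembleVolume}}. Pixels below
#' \code{minMeanFraction} of the maximum mean intensity, or whose fit fails
#' or sticks to the tauD bounds, are masked rather than fatal.
#'
#' @param movie frames x rows x cols array
#' @param frameInterval frame interval (seconds)
#' @param omega focal radius (micrometres, 1/e^2 PSF radius)
#' @param model FCS model passed to \code{\link{fitFcs}}
#' @param lag SOFI correlation lag (frames)
#' @param dRange hue scale range (micrometres^2/s)
#' @param minMeanFraction brightness gate for fitting, as a fraction of the
#'   maximum mean intensity
#' @return A list with \code{sofi}, \code{dmap}, \code{fused}.
#' @export
fcsSofiSlice <- function(movie, frameInterval, omega, model = "brownian1",
                         lag = 1L, dRange = c(0.1, 100),
                         minMeanFraction = 0.05) {
  d <- dim(movie)
  nR <- d[2]; nC <- d[3]
  mu <- colMeans(movie)
  gate <- mu > minMeanFraction * max(mu)
  tauD <- matrix(NA_real_, nR, nC)
  lo_tau <- frameInterval
  for (r in seq_len(nR)) for (c in seq_len(nC)) {
    if (!gate[r, c]) next
    curve <- tryCatch(autocorrelate(movie[, r, c], frameInterval),
                      error = function(e) NULL)
    if (is.null(curve)) next
    # a resolvable decay must rise significantly above the tail noise
    nG <- length(curve@G)
    tailSd <- sd(curve@G[(nG %/% 2):nG])
    if (!is.finite(tailSd) || mean(curve@G[1:3]) < 3 * tailSd) next
    fit <- fitFcs(curve, model, baseline = TRUE)
    if (!fit@converged || !is.finite(fit@tauD)) next
    # reject fits pinned to the lower bound or slower than the largest
    # measured lag (their decay was never observed), and fits whose
    # amplitude does not rise above the curve's own noise floor
    if (fit@tauD <= lo_tau * 1.001 || fit@tauD >= max(curve@lags)) next
    pars <- switch(fit@model,
      brownian1 = c(fit@G0, fit@tauD),
      brownian2 = c(fit@G0, fit@tauD, fit@fraction, fit@tauD2),
      anomalous = c(fit@G0, fit@tauD, fit@alpha))
    noiseFloor <- sd(curve@G - attr(fit, "baseline") -
                       .fcsModelFun(fit@model)(pars, curve@lags))
    if (!is.finite(noiseFloor) || fit@G0 < 5 * noiseFloor) next
    tauD[r, c] <- fit@tauD
  }
  dmap <- diffusionMap(tauD, omega)
  sofi <- sofiXc2(movie, lag)
  fused <- if (any(dmap@validMask))
    fuseImages(sofi, dmap, dRange) else NULL
  list(sofi = sofi, dmap = dmap, fused = fused)
}
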