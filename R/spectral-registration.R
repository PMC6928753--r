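## Fourier-domain registration of multispectral images onto the depth
## sensor's pixel frame: cross-power-spectrum phase correlation for
## translation, Fourier-Mellin (log-polar phase correlation on FFT magnitude
## spectra) for rotation and scale. One shared transform is then applied to
## every band of a reflectance cube.
##
## Pixel conventions used throughout: x = column, y = row, 0-based in the
## geometry formulas; rotations are measured from +x (columns) towards
## +y (rows); scale/rotation act about the image centre ((ncol-1)/2,
## (nrow-1)/2), translation is applied last.

#' Translation estimation by phase correlation
#'
#' Estimates the 2-D shift of \code{moving}'s content relative to
#' \code{fixed} from the peak of the inverse FFT of the normalised
#' cross-power spectrum. For an exact circular integer shift the estimate is
#' exact and the peak equals 1.
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param subpixel if TRUE, refine the peak with a parabolic fit (default
#'   FALSE: integer-pixel output).
#' @param window if TRUE, apply a raised-cosine window before the FFTs
#'   (suppresses wrap-around edge artefacts on non-periodic images; default
#'   FALSE so that circular shifts are recovered exactly).
#' @return list with \code{x0} (column shift), \code{y0} (row shift) such
#'   that \code{moving[r, c] == fixed[r - y0, c - x0]}, and \code{peak}, the
#'   normalised correlation peak in [0, 1].
#' @export
phaseCorrelation <- function(fixed, moving, subpixel = FALSE, window = FALSE) {
  .assertImage(fixed, "fixed"); .assertImage(moving, "moving")
  .assertSameShape(fixed, moving)
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    .mspStop("msp_degenerate_error", "phase correlation needs non-constant images")
  m <- nrow(fixed); n <- ncol(fixed)
  if (window) {
    w <- .hannWindow(m, n)
    fixed <- fixed * w; moving <- moving * w
  }
  Ff <- stats::fft(fixed)
  Fm <- stats::fft(moving)
  cp <- Fm * Conj(Ff)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(stats::fft(cp / mag, inverse = TRUE)) / (m * n)
  k <- which.max(r)
  pr <- (k - 1) %% m          # 0-based row index of peak
  pc <- (k - 1) %/% m         # 0-based col index of peak
  peak <- max(min(r[k], 1), 0)
  y0 <- pr; x0 <- pc
  if (subpixel) {
    ym <- r[(pr - 1) %% m + 1, pc + 1]; yp <- r[(pr + 1) %% m + 1, pc + 1]
    xm <- r[pr + 1, (pc - 1) %% n + 1]; xp <- r[pr + 1, (pc + 1) %% n + 1]
    y0 <- y0 + .parabolicOffset(ym, r[k], yp)
    x0 <- x0 + .parabolicOffset(xm, r[k], xp)
  }
  ## wrap to the signed range (-dim/2, dim/2]
  if (y0 > m / 2) y0 <- y0 - m
  if (x0 > n / 2) x0 <- x0 - n
  list(x0 = x0, y0 = y0, peak = peak)
}

## Log-polar resampling of an FFT magnitude spectrum. Rows are angle bins
## over [0, 180) degrees (conjugate symmetry makes the other half
## redundant), columns are logarithmic radius bins over [1, min(m,n)/2].
.logPolarSpectrum <- function(img, nAngle, nRadius) {
  m <- nrow(img); n <- ncol(img)
  w <- .hannWindow(m, n)
  mag <- .fftshift(Mod(stats::fft(img * w)))
  mag <- log1p(mag)                       # tame the DC/low-frequency dominance
  cy <- floor(m / 2); cx <- floor(n / 2)  # fftshift places DC here (0-based)
  rmin <- 5                               # skip the rotation-insensitive core
  rmax <- min(m, n) / 2
  ang <- (seq_len(nAngle) - 1) * pi / nAngle
  logStep <- log(rmax / rmin) / (nRadius - 1)
  rad <- rmin * exp((seq_len(nRadius) - 1) * logStep)
  xs <- outer(cos(ang), rad)              # nAngle x nRadius
  ys <- outer(sin(ang), rad)
  s <- .bilinearSample(mag, cx + xs, cy + ys)
  lp <- matrix(s$values, nAngle, nRadius)
  lp[is.na(lp)] <- 0
  list(lp = lp, angStepDeg = 180 / nAngle, logStep = logStep)
}

## Rotation/scale candidates from log-polar phase correlation. Returns the
## two 180-degree-ambiguous rotation candidates with the common scale.
.fourierMellinCandidates <- function(fixed, moving,
                                     nAngle = 360L, nRadius = 256L) {
  lpF <- .logPolarSpectrum(fixed, nAngle, nRadius)
  lpM <- .logPolarSpectrum(moving, nAngle, nRadius)
  if (stats::sd(lpF$lp) == 0 || stats::sd(lpM$lp) == 0)
    .mspStop("msp_degenerate_error",
             "rotationally symmetric or constant image: rotation/scale unobservable")
  pc <- phaseCorrelation(lpF$lp, lpM$lp, subpixel = TRUE)
  theta <- pc$y0 * lpF$angStepDeg       # content rotation of moving vs fixed
  sigma <- exp(-pc$x0 * lpF$logStep)    # content scale of moving vs fixed
  list(thetas = c(.wrap180(theta), .wrap180(theta + 180)), sigma = sigma)
}

#' Rotation and scale estimation by the Fourier-Mellin method
#'
#' Both images are windowed, their FFT magnitude spectra are resampled on a
#' log-polar grid (angle bins of 0.5 degrees, logarithmic radius over
#' [1, min(m,n)/2]) and phase-correlated; the translation found there is the
#' rotation/scale of \code{moving}'s content relative to \code{fixed}. The
#' 180-degree ambiguity of the half-spectrum is resolved by compensating the
#' moving image with both candidates and keeping the one with the higher
#' final translation-correlation peak.
#'
#' @inheritParams phaseCorrelation
#' @param nAngle,nRadius log-polar grid size (defaults 360 x 256).
#' @param presmooth Gaussian pre-smoothing sigma in pixels applied to both
#'   images before the spectral analysis (default 1; suppresses pixel-grid
#'   sampling artefacts such as splat combs that would otherwise anchor the
#'   spectrum correlation at the identity).
#' @return list with \code{theta0} (degrees) and \code{sigma} (scale): the
#'   rotation/scale by which \code{moving}'s content exceeds \code{fixed}'s.
#' @export
fourierMellin <- function(fixed, moving, nAngle = 360L, nRadius = 256L,
                          presmooth = 1) {
  .assertImage(fixed, "fixed"); .assertImage(moving, "moving")
  .assertSameShape(fixed, moving)
  fixed <- .gaussBlur(fixed, presmooth)
  moving <- .gaussBlur(moving, presmooth)
  cand <- .fourierMellinCandidates(fixed, moving, nAngle, nRadius)
  best <- .resolveRotationAmbiguity(fixed, moving, cand)
  list(theta0 = best$theta, sigma = cand$sigma)
}

## Try both rotation candidates: undo rotation/scale on `moving`, phase
## correlate against `fixed`, keep the candidate with the higher peak.
.resolveRotationAmbiguity <- function(fixed, moving, cand) {
  best <- NULL
  for (th in cand$thetas) {
    undo <- RegistrationTransform(0, 0, .wrap180(-th), 1 / cand$sigma)
    m2 <- .applyTransformImage(moving, undo, dim(fixed))
    img <- m2$values; img[is.na(img)] <- 0
    pc <- phaseCorrelation(fixed, img, subpixel = TRUE, window = TRUE)
    if (is.null(best) || pc$peak > best$peak)
      best <- list(theta = th, peak = pc$peak, x0 = pc$x0, y0 = pc$y0)
  }
  best
}

#' Full similarity registration of a moving image onto a fixed image
#'
#' Composes [fourierMellin()] (rotation/scale first) with [phaseCorrelation()]
#' on the de-rotated/de-scaled moving image. The returned transform maps the
#' moving image into the fixed image's frame:
#' \code{applyTransform(moving, t)} is aligned with \code{fixed}. (Note the
#' relation to the low-level estimates: if moving content is rotated by
#' \code{+theta} relative to fixed, the aligning transform has
#' \code{theta0 = -theta}.)
#'
#' @inheritParams fourierMellin
#' @return A [RegistrationTransform-class].
#' @export
registerImage <- function(fixed, moving, presmooth = 1) {
  .assertImage(fixed, "fixed"); .assertImage(moving, "moving")
  .assertSameShape(fixed, moving)
  fixed <- .gaussBlur(fixed, presmooth)
  moving <- .gaussBlur(moving, presmooth)
  cand <- .fourierMellinCandidates(fixed, moving)
  best <- .resolveRotationAmbiguity(fixed, moving, cand)
  RegistrationTransform(x0 = -best$x0, y0 = -best$y0,
                        theta0 = .wrap180(-best$theta),
                        sigma = 1 / cand$sigma)
}

#' Invert a registration transform
#'
#' @param t a [RegistrationTransform-class].
#' @return The transform that undoes \code{t} (about the same image centre).
#' @export
invertTransform <- function(t) {
  stopifnot(is(t, "RegistrationTransform"))
  th <- -t@theta0 * pi / 180
  u <- c(t@x0, t@y0)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ui <- -(R %*% u) / t@sigma
  RegistrationTransform(x0 = ui[1], y0 = ui[2], theta0 = .wrap180(-t@theta0),
                        sigma = 1 / t@sigma)
}

## Core resampler: applies `t` to a single image (forward: content is scaled
## by sigma and rotated by theta0 about the centre, then shifted by (x0, y0)).
## Implemented by inverse-mapping every output pixel and sampling bilinearly.
## Returns list(values, ok): `ok` FALSE where the source is outside the image
## or invalid.
.applyTransformImage <- function(img, t, outShape = dim(img), valid = NULL) {
  m <- outShape[1]; n <- outShape[2]
  cyOut <- (m - 1) / 2; cxOut <- (n - 1) / 2
  cyIn <- (nrow(img) - 1) / 2; cxIn <- (ncol(img) - 1) / 2
  xo <- matrix(rep(0:(n - 1), each = m), m, n) - cxOut - t@x0
  yo <- matrix(rep(0:(m - 1), n), m, n) - cyOut - t@y0
  th <- -t@theta0 * pi / 180
  xs <- (cos(th) * xo - sin(th) * yo) / t@sigma + cxIn
  ys <- (sin(th) * xo + cos(th) * yo) / t@sigma + cyIn
  s <- .bilinearSample(img, xs, ys, valid)
  list(values = matrix(s$values, m, n), ok = matrix(s$ok, m, n))
}

#' Apply one registration transform to every band of a spectral cube
#'
#' Every band is resampled with the identical transform into the fixed
#' (output) frame using bilinear interpolation. Output pixels whose source
#' location falls outside the cube, or touches an invalid source pixel, are
#' marked invalid in the mask (their reflectance is NA, never zero-filled).
#'
#' @param cube a [SpectralCube-class].
#' @param t a [RegistrationTransform-class] mapping cube pixels into the
#'   output frame.
#' @param outShape integer(2) rows/cols of the output frame (default: cube
#'   shape).
#' @return A [SpectralCube-class] in the output frame.
#' @export
applyTransform <- function(cube, t, outShape = NULL) {
  stopifnot(is(cube, "SpectralCube"), is(t, "RegistrationTransform"))
  if (t@sigma <= 0) .mspStop("msp_value_error", "sigma must be positive")
  d <- dim(cube@values)
  if (is.null(outShape)) outShape <- d[1:2]
  vals <- array(NA_real_, c(outShape, d[3]))
  ok <- NULL
  for (b in seq_len(d[3])) {
    r <- .applyTransformImage(cube@values[, , b], t, outShape, cube@mask)
    vals[, , b] <- r$values
    ok <- if (is.null(ok)) r$ok else ok & r$ok
  }
  SpectralCube(vals, cube@wavelengths, mask = ok)
}

#' Convert an RGB array to grayscale
#'
#' Fixed ITU-R BT.601 luma weights (0.299, 0.587, 0.114).
#'
#' @param rgb rows x cols x 3 array.
#' @return numeric matrix.
#' @export
rgbToGray <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    .mspStop("msp_dimension_error", "rgb must be rows x cols x 3")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Stack registered channels into one aligned multi-channel array
#'
#' Channel-stacks an RGB (or grayscale) image, a depth image (mm) and a
#' registered reflectance cube that already share the depth sensor's pixel
#' frame. The result is a rows x cols x channels array with channel names
#' ("R","G","B","depth_mm","refl_<nm>") and the cube's wavelengths and
#' validity mask attached as attributes.
#'
#' @param rgb rows x cols x 3 array in [0,1], or a grayscale matrix.
#' @param depth rows x cols matrix of depth in mm (0 = missing).
#' @param cube a registered [SpectralCube-class] of the same pixel shape.
#' @return array with attributes \code{channels}, \code{wavelengths},
#'   \code{spectralMask}.
#' @export
stackRegistered <- function(rgb, depth, cube) {
  stopifnot(is(cube, "SpectralCube"))
  if (is.matrix(rgb)) rgb <- array(rgb, c(dim(rgb), 1L))
  d <- dim(cube@values)
  if (!identical(dim(depth), d[1:2]) || !identical(dim(rgb)[1:2], d[1:2]))
    .mspStop("msp_dimension_error", "rgb, depth and cube must share one pixel frame")
  nc <- dim(rgb)[3]
  out <- array(0, c(d[1], d[2], nc + 1L + d[3]))
  out[, , seq_len(nc)] <- rgb
  out[, , nc + 1L] <- depth
  cv <- cube@values
  cv[is.na(cv)] <- 0   # masked pixels carry the mask, not a magic value
  out[, , nc + 1L + seq_len(d[3])] <- cv
  chan <- c(if (nc == 3L) c("R", "G", "B") else "gray", "depth_mm",
            sprintf("refl_%.2f", cube@wavelengths))
  structure(out, channels = chan, wavelengths = cube@wavelengths,
            spectralMask = cube@mask)
}
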