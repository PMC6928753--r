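## Internal helpers shared across modules.

## Signal a classed error so callers/tests can distinguish failure modes
## without matching message text.
.mspStop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "msp_error", "error", "condition"),
                 list(message = msg, call = call)))
}

.assertImage <- function(x, name = "image", minDim = 2L) {
  if (!is.matrix(x) || !is.numeric(x))
    .mspStop("msp_dimension_error", paste(name, "must be a numeric matrix"))
  if (nrow(x) < minDim || ncol(x) < minDim)
    .mspStop("msp_dimension_error",
             sprintf("%s must be at least %d x %d", name, minDim, minDim))
  if (!all(is.finite(x)))
    .mspStop("msp_degenerate_error", paste(name, "contains non-finite values"))
  invisible(x)
}

.assertSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    .mspStop("msp_dimension_error",
             sprintf("images differ in shape: %s vs %s",
                     paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

## 2-D raised-cosine (Hann) window, separable.
.hannWindow <- function(m, n) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  outer(wr, wc)
}

## Shift zero-frequency component to the centre of a spectrum matrix.
.fftshift <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[c((floor(m / 2) + 1):m, 1:floor(m / 2)),
    c((floor(n / 2) + 1):n, 1:floor(n / 2))]
}

## Wrap an angle in degrees to (-180, 180].
.wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (length(a) == 1L && a == -180) a <- 180
  a[a == -180] <- 180
  a
}

## Parabolic (three-point) refinement of a peak position along one axis.
## y0 is the peak sample, ym/yp its cyclic neighbours; returns offset in
## (-0.5, 0.5).
.parabolicOffset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym - yp) / den
  max(min(off, 0.5), -0.5)
}

## Vectorised bilinear sampling of matrix `img` at fractional 0-based
## positions (x = column, y = row). `valid` is an optional logical matrix of
## source validity. Returns list(values, ok): `ok` FALSE where any of the four
## neighbours falls outside the image or on an invalid source pixel.
.bilinearSample <- function(img, x, y, valid = NULL) {
  m <- nrow(img); n <- ncol(img)
  ok <- x >= 0 & y >= 0 & x <= n - 1 & y <= m - 1
  ## clamp the lower corner so the 4-neighbour stencil stays in range (an
  ## exact hit on the last row/column then has weight 1 on the far corner)
  x0 <- pmin(pmax(floor(x), 0), n - 2)
  y0 <- pmin(pmax(floor(y), 0), m - 2)
  fx <- x - x0; fy <- y - y0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  i00 <- y0 + 1 + m * x0            # [y0, x0] in column-major 1-based
  i01 <- i00 + m                    # [y0, x0+1]
  i10 <- i00 + 1                    # [y0+1, x0]
  i11 <- i00 + m + 1
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i01] +
       (1 - fx) * fy * img[i10] + fx * fy * img[i11]
  if (!is.null(valid))
    ok <- ok & valid[i00] & valid[i01] & valid[i10] & valid[i11]
  v[!ok] <- NA_real_
  list(values = v, ok = ok)
}

## Separable Gaussian blur with edge replication (sigma in pixels).
.gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(2L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma); k <- k / sum(k)
  smooth1 <- function(v) {
    padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
    stats::convolve(padded, rev(k), type = "filter")
  }
  t(apply(apply(img, 2, smooth1), 1, smooth1))
}

## Rotation matrices as printed in the rigid-registration model:
## Rx rotates about X, Rz about Z, Ry about Y ("inverse" sense).
.Rx <- function(a) matrix(c(1, 0, 0,
                            0, cos(a), -sin(a),
                            0, sin(a), cos(a)), 3, 3, byrow = TRUE)
.Rz <- function(b) matrix(c(cos(b), sin(b), 0,
                            -sin(b), cos(b), 0,
                            0, 0, 1), 3, 3, byrow = TRUE)
.Ry <- function(g) matrix(c(cos(g), 0, -sin(g),
                            0, 1, 0,
                            sin(g), 0, cos(g)), 3, 3, byrow = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
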