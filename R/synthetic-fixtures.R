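## Fully synthetic turntable scenes and nutrient datasets with retrievable
## ground truth: a rigid parametric plant (cylindrical stem, ellipsoidal leaf
## patches, cultivation pot) viewed from four angles 90 degrees apart about a
## known rotation axis, spectral cubes corrupted by a known similarity
## transform, sticker frames for axis self-calibration, and dose-structured
## NPK spectra with planted characteristic wavelengths.

## Run `expr` under a fixed RNG state without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Rodrigues rotation about a unit axis by `theta` radians (right-hand rule).
.axisRotation <- function(axis, theta) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)   # column-major skew
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Synthetic turntable scene specification
#'
#' Bundles every ground-truth parameter of a synthetic acquisition: plant and
#' pot geometry, rotation axis, view angles, camera intrinsics, depth noise
#' and quantisation, the known spectral-corruption transform, and the
#' per-band reflectance model. All randomness flows from \code{seed}.
#'
#' Defaults emulate the study conditions: four views 90 degrees apart, a
#' Kinect-like 512 x 424 depth camera about 1.2 m from the plant, 1 mm depth
#' quantisation and 2 mm depth noise (consumer depth-sensor class), and a
#' five-band reflectance cube.
#'
#' @param stemHeight,stemRadius stem cylinder, m.
#' @param leafCount,leafLength,leafWidth ellipsoidal leaf patches, m.
#' @param potRadius,potHeight cultivation pot cylinder, m.
#' @param axisCenter,axisDir turntable rotation axis (m / unit direction).
#' @param viewAngles turntable angles of the acquired views, degrees.
#' @param intrinsics a [cameraIntrinsics()] object.
#' @param imageSize integer(2) depth-image rows, cols.
#' @param depthNoiseSd depth noise standard deviation, mm.
#' @param depthQuant depth quantisation step, mm.
#' @param spectralTransform [RegistrationTransform-class]: the ground-truth
#'   transform mapping the (displaced) spectral image into the depth frame.
#' @param wavelengths band wavelengths, nm.
#' @param leafReflectance,stemReflectance per-band reflectance of canopy
#'   tissue.
#' @param pointDensity surface sampling density, points per square metre.
#' @param seed integer seed.
#' @return list of class "SceneSpec".
#' @export
sceneSpec <- function(stemHeight = 0.35, stemRadius = 0.006,
                      leafCount = 8L, leafLength = 0.11, leafWidth = 0.06,
                      potRadius = 0.08, potHeight = 0.10,
                      axisCenter = c(0.02, -0.32, 1.20),
                      axisDir = c(0.02, 1, 0.03),
                      viewAngles = c(0, 90, 180, 270),
                      intrinsics = cameraIntrinsics(cx = 256, cy = 212,
                                                    fx = 365, fy = 365),
                      imageSize = c(424L, 512L),
                      depthNoiseSd = 2, depthQuant = 1,
                      spectralTransform = RegistrationTransform(
                        x0 = 10, y0 = 6, theta0 = 5, sigma = 1.08),
                      wavelengths = c(451.6, 544.1, 585.7, 696.3, 739.0),
                      leafReflectance = c(0.08, 0.16, 0.14, 0.35, 0.50),
                      stemReflectance = c(0.10, 0.14, 0.13, 0.25, 0.35),
                      pointDensity = 1e6, seed = 1L) {
  axisDir <- axisDir / sqrt(sum(axisDir^2))
  if (length(leafReflectance) != length(wavelengths) ||
      length(stemReflectance) != length(wavelengths))
    .mspStop("msp_value_error", "one reflectance value per band required")
  if (stemHeight <= 0 && leafCount == 0L)
    .mspStop("msp_value_error", "scene needs a stem or leaves")
  structure(list(stemHeight = stemHeight, stemRadius = stemRadius,
                 leafCount = as.integer(leafCount), leafLength = leafLength,
                 leafWidth = leafWidth, potRadius = potRadius,
                 potHeight = potHeight, axisCenter = axisCenter,
                 axisDir = axisDir, viewAngles = viewAngles,
                 intrinsics = intrinsics, imageSize = as.integer(imageSize),
                 depthNoiseSd = depthNoiseSd, depthQuant = depthQuant,
                 spectralTransform = spectralTransform,
                 wavelengths = wavelengths,
                 leafReflectance = leafReflectance,
                 stemReflectance = stemReflectance,
                 pointDensity = pointDensity, seed = as.integer(seed)),
            class = "SceneSpec")
}

## Uniform samples on a cylinder's lateral surface.
.sampleCylinder <- function(n, radius, height, base) {
  u <- stats::runif(n, 0, 2 * pi)
  h <- stats::runif(n, 0, height)
  cbind(base[1] + radius * cos(u), base[2] + h, base[3] + radius * sin(u))
}

#' Generate the ground-truth plant point cloud
#'
#' Samples a rigid parametric plant to the spec's target density: a
#' cylindrical stem along the rotation axis, \code{leafCount} flat
#' elliptical leaf patches attached at heights along the stem, and the pot's
#' lateral surface. Canopy points (stem, leaves) carry per-band reflectance
#' with mild seeded point-to-point variation; pot points have none (their
#' reflectance validity is FALSE), mirroring a spectral camera that only
#' images the canopy.
#'
#' @param spec a [sceneSpec()] object.
#' @return A [MultispectralPointCloud-class] with an attribute
#'   \code{label} (character: "pot", "stem", "leaf" per point).
#' @export
makePlantCloud <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  .withSeed(spec$seed, {
    M <- spec$axisCenter
    areas <- c(stem = 2 * pi * spec$stemRadius * spec$stemHeight,
               leaf = spec$leafCount * pi * (spec$leafLength / 2) *
                 (spec$leafWidth / 2),
               pot = 2 * pi * spec$potRadius * spec$potHeight)
    ns <- round(spec$pointDensity * areas)
    if (sum(ns[c("stem", "leaf")]) == 0)
      .mspStop("msp_value_error", "empty plant: zero stem and leaf points")

    stem <- .sampleCylinder(ns["stem"], spec$stemRadius, spec$stemHeight,
                            base = M)
    pot <- .sampleCylinder(ns["pot"], spec$potRadius, spec$potHeight,
                           base = M - c(0, spec$potHeight, 0))
    leaves <- NULL
    if (spec$leafCount > 0L && ns["leaf"] > 0) {
      per <- diff(round(seq(0, ns["leaf"], length.out = spec$leafCount + 1)))
      leaves <- do.call(rbind, lapply(seq_len(spec$leafCount), function(k) {
        h <- spec$stemHeight * (0.25 + 0.7 * (k - 1) / max(spec$leafCount - 1, 1))
        az <- 2 * pi * ((k - 1) * 0.382 %% 1)      # golden-angle phyllotaxis
        tilt <- stats::runif(1, 0.2, 0.6)
        e1 <- c(cos(az), 0, sin(az))               # leaf axis, outward
        e1 <- cos(tilt) * e1 + sin(tilt) * c(0, 1, 0)
        e2 <- c(-sin(az), 0, cos(az))
        att <- M + c(0, h, 0) + spec$stemRadius * c(cos(az), 0, sin(az))
        r <- sqrt(stats::runif(per[k])); th <- stats::runif(per[k], 0, 2 * pi)
        u <- r * cos(th) * spec$leafLength / 2 + spec$leafLength / 2
        v <- r * sin(th) * spec$leafWidth / 2
        sweep(outer(u, e1) + outer(v, e2), 2, att, "+")
      }))
    }
    xyz <- rbind(pot, stem, leaves)
    label <- c(rep("pot", nrow(pot)), rep("stem", nrow(stem)),
               rep("leaf", if (is.null(leaves)) 0 else nrow(leaves)))
    rgb <- matrix(0, nrow(xyz), 3)
    rgb[label == "pot", ] <- matrix(rep(c(0.55, 0.42, 0.30), each = sum(label == "pot")), ncol = 3)
    rgb[label == "stem", ] <- matrix(rep(c(0.30, 0.45, 0.20), each = sum(label == "stem")), ncol = 3)
    rgb[label == "leaf", ] <- matrix(rep(c(0.20, 0.55, 0.22), each = sum(label == "leaf")), ncol = 3)
    rgb <- pmin(pmax(rgb + matrix(stats::rnorm(length(rgb), 0, 0.02),
                                  ncol = 3), 0), 1)
    B <- length(spec$wavelengths)
    refl <- matrix(NA_real_, nrow(xyz), B)
    rv <- matrix(FALSE, nrow(xyz), B)
    canopy <- label != "pot"
    base <- ifelse(label == "leaf", 1, 0)
    for (b in seq_len(B)) {
      mu <- ifelse(label == "leaf", spec$leafReflectance[b],
                   spec$stemReflectance[b])
      refl[canopy, b] <- pmax(mu[canopy] *
        (1 + stats::rnorm(sum(canopy), 0, 0.03)), 0)
      rv[canopy, b] <- TRUE
    }
    cl <- MultispectralPointCloud(xyz, rgb = rgb, reflectance = refl,
                                  reflValid = rv,
                                  wavelengths = spec$wavelengths)
    attr(cl, "label") <- label
    cl
  })
}

## Z-buffer splat of a cloud onto the pixel grid. Returns index matrix
## (rows x cols) of the nearest point per pixel (NA where empty) and the
## depth (m).
.zbufferProject <- function(xyz, spec, depthBand = 0.003) {
  intr <- spec$intrinsics
  m <- spec$imageSize[1]; n <- spec$imageSize[2]
  z <- xyz[, 3]
  ok <- z > 1e-6
  ie <- intr$cx + xyz[, 1] * intr$fx / z         # exact 0-based col
  je <- intr$cy - xyz[, 2] * intr$fy / z         # exact 0-based row
  i <- round(ie); j <- round(je)
  ok <- ok & i >= 0 & i < n & j >= 0 & j < m
  idx <- which(ok)
  if (!length(idx)) .mspStop("msp_render_error", "no points project into the frame")
  pixOf <- function(sel) j[sel] + 1 + m * i[sel]
  ## pass 1: min z per pixel (classical z-buffer)
  ord <- idx[order(z[idx], decreasing = TRUE)]   # nearest point wins last
  zmin <- matrix(Inf, m, n)
  zmin[pixOf(ord)] <- z[ord]
  ## pass 2: among points within `depthBand` of the pixel's front surface,
  ## the one nearest the pixel centre wins -- its depth best represents the
  ## surface along the pixel-centre ray
  front <- idx[z[idx] <= zmin[pixOf(idx)] + depthBand]
  off <- (ie[front] - i[front])^2 + (je[front] - j[front])^2
  ord2 <- front[order(off, decreasing = TRUE)]
  nearest <- matrix(NA_integer_, m, n)
  nearest[pixOf(ord2)] <- ord2
  nearest
}

#' Render synthetic turntable views of a plant cloud
#'
#' For each view angle the cloud is rotated about the spec's axis
#' (right-hand rule about \code{axisDir}), then z-buffer-projected through
#' the pinhole intrinsics with a 1-pixel splat. Depth (mm) receives Gaussian
#' noise (\code{depthNoiseSd}) and is quantised to \code{depthQuant}. The
#' grayscale and RGB images come from the point colours; the reflectance
#' cube is rendered aligned to the depth frame and then displaced by the
#' inverse of the spec's ground-truth \code{spectralTransform} (so that
#' registering it back recovers that transform). Two sticker calibration
#' frames (coloured point clouds at 0 and 180 degrees) are also emitted.
#'
#' @param cloud the ground-truth [MultispectralPointCloud-class].
#' @param spec the [sceneSpec()] used to build it.
#' @return list with \code{views} (each: \code{depth} mm matrix, \code{gray},
#'   \code{rgb}, \code{cube} (displaced [SpectralCube-class]),
#'   \code{alignedCube}, \code{stack}, \code{gamma}) and
#'   \code{stickerFrames} (clouds \code{obs0}, \code{obs180}).
#' @export
renderViews <- function(cloud, spec) {
  stopifnot(is(cloud, "MultispectralPointCloud"), inherits(spec, "SceneSpec"))
  xyz0 <- coords(cloud)
  .withSeed(spec$seed + 1L, {
    views <- lapply(spec$viewAngles, function(g) {
      R <- .axisRotation(spec$axisDir, g * pi / 180)
      xyz <- sweep(sweep(xyz0, 2, spec$axisCenter) %*% t(R), 2,
                   spec$axisCenter, "+")
      nearest <- .zbufferProject(xyz, spec)
      m <- spec$imageSize[1]; n <- spec$imageSize[2]
      hit <- !is.na(nearest)
      pidx <- nearest[hit]
      depth <- matrix(0, m, n)
      d <- xyz[pidx, 3] * 1000
      if (spec$depthNoiseSd > 0) d <- d + stats::rnorm(length(d), 0, spec$depthNoiseSd)
      if (spec$depthQuant > 0) d <- round(d / spec$depthQuant) * spec$depthQuant
      depth[hit] <- pmax(d, 0)
      rgbArr <- array(0, c(m, n, 3))
      cols <- pointColors(cloud)
      for (k in 1:3) { ch <- matrix(0, m, n); ch[hit] <- cols[pidx, k]; rgbArr[, , k] <- ch }
      gray <- rgbToGray(rgbArr)
      B <- length(spec$wavelengths)
      vals <- array(NA_real_, c(m, n, B))
      msk <- matrix(FALSE, m, n)
      rv <- reflectanceValid(cloud)[pidx, 1]
      for (b in seq_len(B)) {
        ch <- matrix(NA_real_, m, n)
        ch[hit] <- reflectance(cloud)[pidx, b]
        vals[, , b] <- ch
      }
      msk[hit] <- rv
      vals[is.na(vals)] <- 0
      aligned <- SpectralCube(vals, spec$wavelengths, mask = msk)
      displaced <- applyTransform(aligned, invertTransform(spec$spectralTransform))
      dv <- cubeValues(displaced); dv[is.na(dv)] <- 0
      displaced <- SpectralCube(dv, spec$wavelengths, mask = cubeMask(displaced))
      list(depth = depth, gray = 255 * gray, rgb = rgbArr, cube = displaced,
           alignedCube = aligned,
           stack = stackRegistered(rgbArr, depth, aligned), gamma = g)
    })
    list(views = views, stickerFrames = .stickerFrames(spec))
  })
}

## Turntable-disc calibration frames: a grey disc at the axis base with a
## yellow and a red sticker 90 degrees apart, observed at 0 and 180 degrees.
.stickerFrames <- function(spec) {
  M <- spec$axisCenter; P <- spec$axisDir
  ## orthonormal frame of the disc plane
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * P) * P
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(P[2] * e1[3] - P[3] * e1[2], P[3] * e1[1] - P[1] * e1[3],
          P[1] * e1[2] - P[2] * e1[1])
  ## one rigid disc + sticker point set, observed at both turntable angles
  n <- 4000L
  r <- spec$potRadius * 1.4 * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  pts <- sweep(outer(r * cos(th), e1) + outer(r * sin(th), e2), 2, M, "+")
  col <- matrix(rep(c(0.45, 0.45, 0.45), each = n), ncol = 3)
  sticker <- function(az, colr) {
    c0 <- M + spec$potRadius * 1.1 * (cos(az) * e1 + sin(az) * e2)
    ns <- 200L
    rr <- 0.008 * sqrt(stats::runif(ns)); tt <- stats::runif(ns, 0, 2 * pi)
    sp <- sweep(outer(rr * cos(tt), e1) + outer(rr * sin(tt), e2), 2, c0, "+")
    list(p = sp, col = matrix(rep(colr, each = ns), ncol = 3))
  }
  y <- sticker(0, c(0.95, 0.9, 0.05)); rd <- sticker(pi / 2, c(0.9, 0.08, 0.08))
  pts <- rbind(pts, y$p, rd$p); col <- rbind(col, y$col, rd$col)
  discCloud <- function(angle) {
    R <- .axisRotation(P, angle)
    MultispectralPointCloud(sweep(sweep(pts, 2, M) %*% t(R), 2, M, "+"),
                            rgb = col)
  }
  list(obs0 = discCloud(0), obs180 = discCloud(pi),
       stickerCenters0 = list(
         yellow = M + spec$potRadius * 1.1 * e1,
         red = M + spec$potRadius * 1.1 * e2))
}

#' Default instrument wavelength grid
#'
#' A 128-band grid spanning 400-1100 nm whose spacing matches the
#' hyperspectral imager emulated by the generator; it contains the six
#' infrared-interference wavelengths (841.42-868.65 nm) exactly, so the
#' default interference-band removal maps 128 bands onto 122.
#'
#' @return numeric(128), strictly increasing, nm.
#' @export
defaultWavelengthGrid <- function() {
  wl <- seq(400, 1100, length.out = 128)
  wl[82:87] <- c(841.42, 846.85, 852.30, 857.74, 863.19, 868.65)
  wl
}

#' The six infrared-interference wavelengths (nm)
#' @return numeric(6).
#' @export
interferenceBands <- function() c(841.42, 846.85, 852.30, 857.74, 863.19, 868.65)

#' Planted-signal spectra for selector validation
#'
#' Builds spectra with per-sample smooth random variation around a
#' vegetation-like baseline and then a response depending linearly on the
#' reflectance at \code{planted} wavelength indices plus noise at the given
#' signal-to-noise ratio. Because the response is constructed from exactly
#' those columns, a wavelength selector should recover them.
#'
#' @param n samples.
#' @param wavelengths band grid, nm.
#' @param planted indices of the signal-carrying bands.
#' @param snr ratio of signal standard deviation to response-noise standard
#'   deviation (default 10).
#' @param seed integer seed.
#' @return list with \code{spectra} ([SpectraMatrix-class]), \code{y},
#'   \code{planted} (nm) and \code{weights}.
#' @export
makePlantedSignalSpectra <- function(n = 200L,
                                     wavelengths = defaultWavelengthGrid(),
                                     planted = c(10, 27, 35, 55, 63),
                                     snr = 10, seed = 1L) {
  p <- length(wavelengths)
  if (any(planted > p)) .mspStop("msp_value_error", "planted index out of range")
  .withSeed(seed, {
    x <- seq(0, 1, length.out = p)
    baseline <- 0.06 + 0.03 * exp(-((x - 0.2) / 0.08)^2) +
      0.42 / (1 + exp(-(x - 0.45) / 0.03))
    Z <- matrix(stats::rnorm(n * (p + 6)), n, p + 6)
    k <- stats::dnorm(-3:3, sd = 1.0); k <- k / sqrt(sum(k^2))
    Zs <- t(apply(Z, 1, function(r) stats::convolve(r, rev(k), type = "filter")))
    spectra <- pmax(matrix(rep(baseline, each = n), n, p) + 0.05 * Zs, 0)
    w <- rep(c(1, -1), length.out = length(planted))
    signal <- as.numeric(spectra[, planted, drop = FALSE] %*% w)
    y <- signal + stats::rnorm(n, 0, stats::sd(signal) / snr)
    list(spectra = SpectraMatrix(spectra, wavelengths), y = y,
         planted = wavelengths[planted], weights = w)
  })
}

#' Generate a dose-structured synthetic NPK spectra dataset
#'
#' Samples are organised in five nutrient-dose groups (25, 75, 100, 150 and
#' 200 percent of a standard formula, \code{n}/5 plants per group). Each
#' nutrient content follows a saturating monotone dose response with
#' per-plant jitter. Reflectance spectra are a smooth vegetation-like
#' baseline plus, for each nutrient, Gaussian bumps centred on that
#' nutrient's planted characteristic wavelengths whose amplitude is linear
#' in the nutrient's standardised content, plus smooth correlated noise.
#' With \code{noiseSd = 0} the correlation between a nutrient and its
#' planted bands is exactly 1 in magnitude.
#'
#' @param n number of samples (default 60, divisible by 5).
#' @param wavelengths band grid, nm (default [defaultWavelengthGrid()]).
#' @param planted named list (N, P, K) of planted wavelength indices; the
#'   default plants 5 bands per nutrient, disjoint across nutrients.
#' @param effectSize bump amplitude per standard deviation of nutrient
#'   content (reflectance units; default 0.03).
#' @param noiseSd standard deviation of the correlated spectral noise
#'   (default 0.003, i.e. signal-to-noise 10 at the planted bands).
#' @param seed integer seed.
#' @return list with \code{spectra} ([SpectraMatrix-class]), \code{npk}
#'   (data.frame N, P, K in mg/g plus \code{dose}), and \code{planted}
#'   (named list of planted wavelengths, nm).
#' @export
makeNpkDataset <- function(n = 60L, wavelengths = defaultWavelengthGrid(),
                           planted = NULL, effectSize = 0.03,
                           noiseSd = 0.003, seed = 1L) {
  if (n < 10L) .mspStop("msp_value_error", "need n >= 10 samples")
  p <- length(wavelengths)
  ## default signatures are spaced >= 8 bands apart (across nutrients too)
  ## so the per-band cross-talk of the Gaussian bumps is negligible, and
  ## avoid the interference-band indices (82-87)
  if (is.null(planted))
    planted <- list(N = c(6, 30, 54, 78, 112), P = c(14, 38, 62, 96, 120),
                    K = c(22, 46, 70, 104, 128))
  if (any(unlist(planted) > p))
    .mspStop("msp_value_error", "planted indices exceed the wavelength grid")
  .withSeed(seed, {
    doses <- rep(c(0.25, 0.75, 1.0, 1.5, 2.0), length.out = n)
    doses <- sort(doses)
    resp <- function(base, span, K) {
      mu <- base + span * doses / (doses + K)
      mu * (1 + stats::rnorm(n, 0, 0.05))
    }
    npk <- data.frame(N = resp(18, 40, 0.8), P = resp(2.5, 7, 1.0),
                      K = resp(14, 30, 0.9), dose = doses)
    ## smooth vegetation-like baseline: low visible, red edge, NIR plateau;
    ## the visible floor leaves headroom for downward nutrient signatures so
    ## reflectance stays positive without clipping
    x <- seq(0, 1, length.out = p)
    baseline <- 0.15 + 0.03 * exp(-((x - 0.2) / 0.08)^2) +
      0.40 / (1 + exp(-(x - 0.45) / 0.03))
    spectra <- matrix(rep(baseline, each = n), n, p)
    bump <- function(center, width = 1.2)
      exp(-0.5 * ((seq_len(p) - center) / width)^2)
    for (nu in names(planted)) {
      zval <- as.numeric(scale(npk[[nu]]))
      for (ix in planted[[nu]])
        spectra <- spectra + effectSize * outer(zval, bump(ix))
    }
    if (noiseSd > 0) {
      noise <- matrix(stats::rnorm(n * (p + 8)), n, p + 8)
      k <- stats::dnorm(-4:4, sd = 1.5); k <- k / sqrt(sum(k^2))
      sm <- t(apply(noise, 1, function(r) stats::convolve(r, rev(k), type = "filter")))
      spectra <- spectra + noiseSd * sm[, seq_len(p)]
    }
    spectra <- pmax(spectra, 0)
    list(spectra = SpectraMatrix(spectra, wavelengths),
         npk = npk,
         planted = lapply(planted, function(ix) wavelengths[ix]))
  })
}
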