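# Shared fixtures, built in code. Expensive scene renders are cached per
# test run.

# Smooth textured image (band-limited noise): FFT-friendly registration
# target with energy at mid frequencies.
mkTexturedImage <- function(n = 256L, seed = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  K <- matrix(0, n, n)
  k <- outer(dnorm(-7:7, sd = 3), dnorm(-7:7, sd = 3))
  K[1:15, 1:15] <- k / sum(k)
  sm <- Re(fft(fft(z) * fft(K), inverse = TRUE)) / (n * n)
  sm <- sm - min(sm)
  255 * sm / max(sm)
}

# Noiseless linear regression fixture (42/18-style split done by callers).
mkLinearRegressionData <- function(n = 60L, p = 5L, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.1, 0.6), n, p)
  w <- c(30, -12, 8, 20, -5)[seq_len(p)]
  list(X = X, y = as.numeric(X %*% w) + 10)
}

# Cached synthetic turntable scenes (ground truth + rendered views +
# sticker frames + axis calibration from the sticker frames).
.fixtureEnv <- new.env(parent = emptyenv())

sceneFixture <- function(noise = 0, seed = 3L, density = 1e6) {
  key <- sprintf("scene_%g_%d_%g", noise, seed, density)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  spec <- sceneSpec(seed = seed, depthNoiseSd = noise, pointDensity = density)
  cloud <- makePlantCloud(spec)
  scene <- renderViews(cloud, spec)
  calib <- estimateAxis(stickerCentroids(scene$stickerFrames$obs0),
                        stickerCentroids(scene$stickerFrames$obs180))
  fx <- list(spec = spec, cloud = cloud, scene = scene, calib = calib)
  .fixtureEnv[[key]] <- fx
  fx
}

# Mean-band grayscale of a cube on the 8-bit scale (NA-masked pixels -> 0).
meanBandImage <- function(cube) {
  v <- cubeValues(cube)
  m <- apply(v, c(1, 2), function(x) mean(x, na.rm = TRUE))
  m[is.na(m)] <- 0
  255 * m / max(m)
}
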