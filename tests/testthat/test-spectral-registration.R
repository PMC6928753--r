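test_that("phase correlation recovers circular integer shifts exactly", {
  img <- mkTexturedImage(seed = 1)
  r <- phaseCorrelation(img, img)
  expect_equal(c(r$x0, r$y0), c(0, 0))
  expect_equal(r$peak, 1, tolerance = 1e-10)

  ## content shifted +7 columns, -4 rows: moving(r, c) = fixed(r + 4, c - 7)
  mv <- img[((0:255 + 4) %% 256) + 1, ((0:255 - 7) %% 256) + 1]
  r <- phaseCorrelation(img, mv)
  expect_equal(c(r$x0, r$y0), c(7, -4))

  set.seed(20)
  for (k in 1:20) {
    dx <- sample(-100:100, 1); dy <- sample(-100:100, 1)
    mv <- img[((0:255 - dy) %% 256) + 1, ((0:255 - dx) %% 256) + 1]
    r <- phaseCorrelation(img, mv)
    expect_equal(c(r$x0, r$y0), c(dx, dy))
  }
})

test_that("phase correlation matches a brute-force shift search on small images", {
  n <- 16L
  img <- mkTexturedImage(n, seed = 7)
  set.seed(7)
  for (rep in 1:5) {
    dx <- sample(0:(n - 1), 1); dy <- sample(0:(n - 1), 1)
    mv <- img[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(n) - 1 - dx) %% n) + 1]
    ## brute force: correlation over every circular shift
    best <- c(NA, NA); bestv <- -Inf
    for (sx in 0:(n - 1)) for (sy in 0:(n - 1)) {
      shifted <- mv[((seq_len(n) - 1 + sy) %% n) + 1, ((seq_len(n) - 1 + sx) %% n) + 1]
      v <- sum(shifted * img)
      if (v > bestv) { bestv <- v; best <- c(sx, sy) }
    }
    r <- phaseCorrelation(img, mv)
    expect_equal(c(r$x0 %% n, r$y0 %% n), best)
  }
})

test_that("phase correlation rejects degenerate input", {
  img <- mkTexturedImage()
  expect_error(phaseCorrelation(img, matrix(5, 256, 256)),
               class = "msp_degenerate_error")
  expect_error(phaseCorrelation(img, img[1:100, 1:100]),
               class = "msp_dimension_error")
})

test_that("Fourier-Mellin estimates rotation and scale of the moving content", {
  img <- mkTexturedImage(seed = 2)
  fm <- fourierMellin(img, img)
  expect_equal(fm$theta0, 0, tolerance = 0.1)
  expect_equal(fm$sigma, 1, tolerance = 0.002)

  mkMoving <- function(theta, sigma) {
    mv <- applyTransform(SpectralCube(img, 500),
                         RegistrationTransform(0, 0, theta, sigma))
    out <- cubeValues(mv)[, , 1]; out[is.na(out)] <- 0; out
  }
  fm <- fourierMellin(img, mkMoving(15, 1.25))
  expect_equal(fm$theta0, 15, tolerance = 1)
  expect_equal(fm$sigma, 1.25, tolerance = 1.25 * 0.02)

  fm <- fourierMellin(img, mkMoving(0, 0.8))
  expect_equal(fm$theta0, 0, tolerance = 1)
  expect_equal(fm$sigma, 0.8, tolerance = 0.8 * 0.02)
})

test_that("Fourier-Mellin is invariant to pure translation of the moving image", {
  img <- mkTexturedImage(seed = 3)
  mv <- img[((0:255 - 21) %% 256) + 1, ((0:255 - 33) %% 256) + 1]
  fm <- fourierMellin(img, mv)
  expect_equal(fm$theta0, 0, tolerance = 0.5)
  expect_equal(fm$sigma, 1, tolerance = 0.005)
})

test_that("registerImage recovers a composite transform and aligns the image", {
  img <- mkTexturedImage(seed = 4)
  est <- registerImage(img, img)
  expect_equal(c(est@x0, est@y0, est@theta0, est@sigma), c(0, 0, 0, 1),
               tolerance = 1e-6)

  truth <- RegistrationTransform(10, 5, 8, 1.1)
  mv <- applyTransform(SpectralCube(img, 500), invertTransform(truth))
  mvImg <- cubeValues(mv)[, , 1]; mvImg[is.na(mvImg)] <- 0
  est <- registerImage(img, mvImg)
  expect_equal(est@x0, truth@x0, tolerance = 1)
  expect_equal(est@y0, truth@y0, tolerance = 1)
  expect_equal(est@theta0, truth@theta0, tolerance = 1)
  expect_equal(est@sigma, truth@sigma, tolerance = 1.1 * 0.02)

  ## applying the estimate re-aligns the moving image (grayscale similarity
  ## oracle on pixels with a valid source)
  reg <- applyTransform(SpectralCube(mvImg, 500), est)
  ok <- cubeMask(reg)
  D <- 1 - sum(abs(cubeValues(reg)[, , 1][ok] - img[ok])) / (sum(ok) * 255)
  expect_gte(D, 0.98)
})

test_that("applyTransform resamples all bands identically and tracks validity", {
  ## smooth content: the inverse round-trip contract is an interpolation
  ## statement, meaningful only below the Nyquist limit
  base <- mkTexturedImage(32, seed = 12) / 255
  vals <- array(c(base[1:20, 1:30], 0.5 * base[1:20, 1:30]), c(20, 30, 2))
  cube <- SpectralCube(vals, c(500, 600))

  idcube <- applyTransform(cube, RegistrationTransform())
  expect_equal(cubeValues(idcube), vals, tolerance = 1e-12)
  expect_true(all(cubeMask(idcube)))

  ## pure shift moves a bright pixel by +5 columns and invalidates the
  ## vacated border
  one <- matrix(0, 20, 30); one[11, 8] <- 1
  sh <- applyTransform(SpectralCube(one, 500), RegistrationTransform(x0 = 5))
  expect_equal(which(cubeValues(sh)[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 11, col = 13))
  expect_false(any(cubeMask(sh)[, 1:5]))
  expect_true(all(cubeMask(sh)[, 6:30]))

  ## forward then inverse returns the original on interior pixels
  t <- RegistrationTransform(3, -2, 10, 1.05)
  back <- applyTransform(applyTransform(cube, t), invertTransform(t))
  interior <- 6:15
  expect_equal(cubeValues(back)[interior, interior, ],
               vals[interior, interior, ], tolerance = 0.05)
  expect_error(RegistrationTransform(sigma = 0), "sigma")
})

test_that("stackRegistered stacks channels with metadata and round-trips", {
  m <- 12L; n <- 10L
  rgb <- array(round(runif(m * n * 3) * 256) / 256, c(m, n, 3))
  depth <- matrix(round(runif(m * n, 500, 2000)), m, n)
  cube <- SpectralCube(array(round(runif(m * n * 5) * 256) / 256, c(m, n, 5)),
                       c(451.6, 544.1, 585.7, 696.3, 739.0))
  st <- stackRegistered(rgb, depth, cube)
  expect_equal(dim(st)[3], 9L)   # 3 RGB + depth + 5 bands
  expect_equal(attr(st, "wavelengths"), wavelengths(cube))
  expect_equal(grep("^refl_", attr(st, "channels")), 5:9)

  path <- tempfile(fileext = ".tif")
  writeChannelStack(st, path)
  back <- readChannelStack(path)
  expect_equal(as.numeric(back), as.numeric(st), tolerance = 1e-6)
  expect_equal(attr(back, "channels"), attr(st, "channels"))
  expect_equal(attr(back, "wavelengths"), attr(st, "wavelengths"))

  expect_error(stackRegistered(rgb, depth[1:5, ], cube),
               class = "msp_dimension_error")
})
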