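test_that("depthToCloud implements the pinhole back-projection exactly", {
  intr <- cameraIntrinsics(cx = 256, cy = 212, fx = 365, fy = 365)
  depth <- matrix(0, 424, 512)
  depth[213, 257] <- 1000          # pixel (i, j) = (256, 212), 0-based
  depth[113, 357] <- 1825          # pixel (i, j) = (356, 112)
  cl <- depthToCloud(depth, intr)
  xyz <- coords(cl)[order(coords(cl)[, 3]), ]
  expect_equal(xyz[1, ], c(0, 0, 1.0))
  expect_equal(xyz[2, ], c(0.5, 0.5, 1.825))
  expect_equal(nPoints(cl), 2L)    # zero-depth pixels produce no points

  expect_error(depthToCloud(matrix(0, 4, 4), intr),
               class = "msp_empty_cloud_error")
})

test_that("depthToCloud is exactly invertible through the pinhole model", {
  set.seed(3)
  intr <- cameraIntrinsics(cx = 31.5, cy = 23.5, fx = 80, fy = 80)
  depth <- matrix(0, 48, 64)
  sel <- sample(length(depth), 200)
  depth[sel] <- sample(500:3000, 200, replace = TRUE)
  cl <- depthToCloud(depth, intr)
  xyz <- coords(cl)
  i <- round(intr$cx + xyz[, 1] * intr$fx / xyz[, 3])
  j <- round(intr$cy - xyz[, 2] * intr$fy / xyz[, 3])
  d <- round(xyz[, 3] * 1000)
  expect_true(all(depth[cbind(j + 1, i + 1)] == d))
})

test_that("roiFilter keeps exactly the points in the closed box", {
  set.seed(8)
  xyz <- matrix(runif(300), 100, 3)
  cl <- MultispectralPointCloud(xyz, reflectance = matrix(runif(100), 100, 1),
                                wavelengths = 500)
  all <- roiFilter(cl, list(min = c(-1, -1, -1), max = c(2, 2, 2)))
  expect_equal(coords(all), xyz)
  none <- roiFilter(cl, list(min = c(5, 5, 5), max = c(6, 6, 6)))
  expect_equal(nPoints(none), 0L)

  box <- list(min = c(0, 0, 0), max = c(0.5, 0.5, 0.5))
  kept <- roiFilter(cl, box)
  inside <- apply(xyz, 1, function(p) all(p >= 0 & p <= 0.5))
  expect_equal(coords(kept), xyz[inside, , drop = FALSE])
  expect_equal(reflectance(kept), reflectance(cl)[inside, , drop = FALSE])
  expect_error(roiFilter(cl, list(min = c(1, 0, 0), max = c(0, 1, 1))),
               class = "msp_value_error")
})

test_that("roughRegister applies the axis-alignment + inverse-view rotation", {
  ## axis already +Y through origin, reference view: identity
  cal <- AxisCalibration(c(0, 0, 0), c(0, 1, 0))
  xyz <- matrix(rnorm(30), 10, 3)
  cl <- MultispectralPointCloud(xyz)
  expect_equal(coords(roughRegister(cl, cal, 0)), xyz, tolerance = 1e-12)

  ## +Y axis through (0.1, 0, 0.8): pure translation
  cal2 <- AxisCalibration(c(0.1, 0, 0.8), c(0, 1, 0))
  p <- MultispectralPointCloud(matrix(c(0.1, 0.2, 0.8), 1, 3))
  expect_equal(as.numeric(coords(roughRegister(p, cal2, 0))), c(0, 0.2, 0),
               tolerance = 1e-12)

  ## rigid map preserves pairwise distances
  cal3 <- AxisCalibration(c(0.02, -0.32, 1.2), c(0.02, 1, 0.03) / sqrt(sum(c(0.02, 1, 0.03)^2)))
  reg <- roughRegister(cl, cal3, 137)
  expect_equal(as.numeric(dist(coords(reg))), as.numeric(dist(xyz)),
               tolerance = 1e-9)

  expect_error(roughRegister(cl, cal, 360), class = "msp_value_error")
})

test_that("a physically rotated view rough-registers onto the reference view", {
  fx <- sceneFixture(noise = 0)
  cl <- fx$cloud; spec <- fx$spec; cal <- fx$calib
  R <- msplant3d:::.axisRotation(spec$axisDir, pi / 2)
  xyz90 <- sweep(sweep(coords(cl), 2, spec$axisCenter) %*% t(R), 2,
                 spec$axisCenter, "+")
  r0 <- roughRegister(cl, cal, 0)
  r90 <- roughRegister(MultispectralPointCloud(xyz90), cal, 90)
  err <- sqrt(rowSums((coords(r0) - coords(r90))^2))
  expect_lt(mean(err), 1e-3)   # < 1 mm, noise-free
})

test_that("ICP refines small rigid offsets to sub-half-millimetre", {
  fx <- sceneFixture(noise = 0)
  xyz <- coords(fx$cloud)
  set.seed(21)
  xyz <- xyz[sample(nrow(xyz), 4000), ]

  ## identity case
  icp <- icpRefine(xyz, xyz)
  expect_lt(icp$rmse, 1e-9)
  expect_equal(icp$R, diag(3), tolerance = 1e-9)

  ## 5 mm displacement with ~60 % overlap
  cut <- quantile(xyz[, 2], 0.4)
  src <- xyz[xyz[, 2] >= cut, ]
  tgt <- sweep(xyz, 2, c(0.005, 0, 0), "+")
  icp <- icpRefine(src, tgt)
  expect_lt(sqrt(sum((icp$t - c(0.005, 0, 0))^2)), 5e-4)
  expect_lt(max(abs(icp$R - diag(3))), 1e-2)

  ## inlier RMSE is non-increasing along the iteration history
  expect_true(all(diff(icp$history) <= 1e-9))

  ## gating failure
  far <- sweep(xyz, 2, c(1, 0, 0), "+")
  expect_error(icpRefine(xyz, far, maxCorrDist = 0.001),
               class = "msp_registration_error")
  expect_error(icpRefine(matrix(0, 0, 3), xyz),
               class = "msp_empty_cloud_error")
})

test_that("reconstructViews chains views in order with provenance", {
  fx <- sceneFixture(noise = 0)
  views <- lapply(fx$scene$views, function(v)
    list(depth = v$depth, stack = v$stack, gamma = v$gamma))

  expect_error(reconstructViews(views[1], fx$calib, fx$spec$intrinsics),
               class = "msp_value_error")

  rec <- reconstructViews(views, fx$calib, fx$spec$intrinsics)
  perView <- vapply(views, function(v)
    nPoints(depthToCloud(v$depth, fx$spec$intrinsics)), integer(1))
  expect_equal(nPoints(rec), sum(perView))
  expect_equal(sort(unique(viewIds(rec))), 1:4)
  expect_equal(tabulate(viewIds(rec)), perView)

  ## spectral attributes ride along
  expect_equal(wavelengths(rec), fx$spec$wavelengths)
  expect_gt(mean(reflectanceValid(rec)), 0.3)  # canopy yes, pot no

  ## deterministic given fixed inputs
  rec2 <- reconstructViews(views, fx$calib, fx$spec$intrinsics)
  expect_identical(coords(rec), coords(rec2))
})

test_that("noise-free multiview reconstruction reaches sub-quantisation error", {
  fx <- sceneFixture(noise = 0)
  views <- lapply(fx$scene$views, function(v)
    list(depth = v$depth, stack = v$stack, gamma = v$gamma))
  rec <- reconstructViews(views, fx$calib, fx$spec$intrinsics)
  gt <- roughRegister(fx$cloud, fx$calib, 0)
  hd <- hdStats(100 * hausdorffSet(coords(rec), coords(gt)))
  expect_lt(hd@hdAvg, 0.1)   # below the 1 mm depth quantisation, in cm
})
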