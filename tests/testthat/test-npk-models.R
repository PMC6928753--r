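test_that("extractCanopyReflectance averages valid points per band", {
  cl <- MultispectralPointCloud(matrix(0, 3, 3),
                                reflectance = matrix(0.5, 3, 2),
                                wavelengths = c(500, 600))
  expect_equal(unname(extractCanopyReflectance(cl)), c(0.5, 0.5),
               ignore_attr = TRUE)

  refl <- matrix(c(0.2, 0.6, 0.9), 3, 1)
  rv <- matrix(c(TRUE, TRUE, FALSE), 3, 1)
  cl2 <- MultispectralPointCloud(matrix(0, 3, 3), reflectance = refl,
                                 reflValid = rv, wavelengths = 500)
  expect_equal(unname(extractCanopyReflectance(cl2, 500)), 0.4,
               ignore_attr = TRUE)
  expect_error(extractCanopyReflectance(cl2, 777), class = "msp_lookup_error")
})

test_that("BPANN recovers a noiseless linear map and is seed-deterministic", {
  d <- mkLinearRegressionData(seed = 1)
  sp <- calibrationSplit(60, 42, seed = 1)
  fit <- fitBPANN(d$X[sp$calib, ], d$y[sp$calib], seed = 7)
  ev <- evaluateModel(fit, d$X[sp$calib, ], d$y[sp$calib],
                      d$X[sp$pred, ], d$y[sp$pred])
  expect_gte(ev$Rp2, 0.99)

  fit2 <- fitBPANN(d$X[sp$calib, ], d$y[sp$calib], seed = 7)
  expect_identical(predict(fit, d$X), predict(fit2, d$X))

  cf <- fitBPANN(d$X[sp$calib, ], rep(3, 42), seed = 7)
  expect_equal(stats::sd(predict(cf, d$X)), 0, tolerance = 1e-2)
  expect_lt(sqrt(mean((predict(cf, d$X[sp$calib, ]) - 3)^2)), 1e-2)
  expect_error(fitBPANN(d$X, c(NA, d$y[-1])), class = "msp_value_error")
})

test_that("SVMR fits noiseless linear data and respects standardisation", {
  d <- mkLinearRegressionData(seed = 2)
  sp <- calibrationSplit(60, 42, seed = 2)
  fit <- fitSVMR(d$X[sp$calib, ], d$y[sp$calib], kernelScale = "auto",
                 cost = 100, epsilon = 0.001)
  ev <- evaluateModel(fit, d$X[sp$calib, ], d$y[sp$calib],
                      d$X[sp$pred, ], d$y[sp$pred])
  expect_gte(ev$Rp2, 0.95)

  ## duplicate rows predict identically
  p <- predict(fit, d$X[c(1, 1, 5), ])
  expect_equal(p[1], p[2])

  ## feature-wise affine rescaling is absorbed by standardisation
  scaleMat <- matrix(rep(c(10, 0.1, 3, 1, 100), each = 42), 42, 5)
  fitScaled <- fitSVMR(d$X[sp$calib, ] * scaleMat +
                         matrix(rep(1:5, each = 42), 42, 5),
                       d$y[sp$calib], kernelScale = "auto",
                       cost = 100, epsilon = 0.001)
  pRaw <- predict(fit, d$X[sp$pred, ])
  pScaled <- predict(fitScaled, d$X[sp$pred, ] *
                       matrix(rep(c(10, 0.1, 3, 1, 100), each = 18), 18, 5) +
                       matrix(rep(1:5, each = 18), 18, 5))
  expect_equal(pRaw, pScaled, tolerance = 1e-6)
})

test_that("GPR interpolates near-noiseless data and yields valid variances", {
  set.seed(9)
  X <- matrix(seq(0, 1, length.out = 42), ncol = 1)
  y <- sin(2 * pi * X[, 1]) + 2
  fit <- fitGPR(X, y, seed = 3)
  expect_lt(max(abs(predict(fit, X) - y)), 1e-3)

  Xt <- matrix(seq(0.05, 0.95, length.out = 30), ncol = 1)
  yt <- sin(2 * pi * Xt[, 1]) + 2
  ev <- evaluateModel(fit, X, y, Xt, yt)
  expect_gte(ev$Rp2, 0.99)

  pv <- predict(fit, rbind(X, Xt, matrix(c(-0.5, 1.5), ncol = 1)),
                se.fit = TRUE)
  expect_true(all(pv$se.fit >= 0))
})

test_that("evaluateModel reproduces hand-computed RMSEP and RE", {
  predictFixed <- function(object, newdata, ...) object$v[seq_len(nrow(newdata))]
  registerS3method("predict", "fixedpred", predictFixed,
                   envir = asNamespace("stats"))
  m <- structure(list(v = c(11, 19)), class = "fixedpred")
  ev <- evaluateModel(m, Xc = matrix(0, 2, 1), yc = c(11, 19),
                      Xp = matrix(0, 2, 1), yp = c(10, 20))
  expect_equal(ev$RMSEP, 1)
  expect_equal(ev$RE, 7.5)
  expect_equal(ev$Rc2, 1); expect_equal(ev$RMSEC, 0)

  mConst <- structure(list(v = c(5, 5)), class = "fixedpred")
  evc <- evaluateModel(mConst, matrix(0, 2, 1), c(11, 19),
                       matrix(0, 2, 1), c(10, 20))
  expect_true(is.na(evc$Rp2))
  expect_true(attr(evc, "undefinedR2"))
  expect_error(evaluateModel(m, matrix(0, 2, 1), c(1, 2),
                             matrix(0, 2, 1), c(0, 2)),
               class = "msp_value_error")
})

test_that("wet-chemistry mass fractions follow the titration formulas", {
  expect_equal(nitrogenMassFraction(V2 = 20, V0 = 0.5, c = 0.05,
                                    V1 = 50, V = 250, m = 0.5), 13.65)
  expect_equal(nitrogenMassFraction(10, 10, 0.05, 50, 250, 0.5), 0)
  expect_equal(nitrogenMassFraction(20, 0.5, 0.05, 50, 250, 1),
               13.65 / 2)   # doubling the mass halves the fraction

  expect_equal(phosphorusMassFraction(rho = 2, V = 100, V1 = 10, V2 = 50,
                                      m = 0.5), 0.2)
  expect_equal(phosphorusMassFraction(0, 100, 10, 50, 0.5), 0)
  expect_equal(phosphorusMassFraction(4, 100, 10, 50, 0.5), 0.4)  # linear in rho

  expect_equal(potassiumMassFraction(rho = 5, rho0 = 0.2, V = 100, V1 = 10,
                                     V2 = 50, m = 0.5), 0.48)
  expect_equal(potassiumMassFraction(0.2, 0.2, 100, 10, 50, 0.5), 0)
  expect_equal(potassiumMassFraction(0.2, 5, 100, 10, 50, 0.5), -0.48)

  expect_error(nitrogenMassFraction(20, 0.5, 0.05, 50, 250, 0),
               class = "msp_value_error")
  expect_error(phosphorusMassFraction(2, 100, 0, 50, 0.5),
               class = "msp_value_error")
})

test_that("runModelMatrix emits one evaluated row per grid cell", {
  d <- mkLinearRegressionData(seed = 3)
  npk <- data.frame(N = d$y, P = d$y / 10 + 1, K = d$y / 2 + 3)
  feats <- list(AOV1 = d$X, `3DROI` = d$X + 0.01)

  one <- runModelMatrix(feats["AOV1"], npk, nutrients = "N",
                        methods = "SVMR")
  expect_equal(nrow(one), 1L)

  tab <- runModelMatrix(feats, npk, methods = c("SVMR", "GPR"), seed = 4)
  expect_equal(nrow(tab), 3L * 2L * 2L)   # nutrients x sources x methods
  expect_setequal(unique(tab$Input), c("AOV1", "3DROI"))
  expect_true(all(c("Rc2", "RMSEC", "Rp2", "RMSEP", "RE") %in% names(tab)))
  tab2 <- runModelMatrix(feats, npk, methods = c("SVMR", "GPR"), seed = 4)
  expect_identical(tab, tab2)
})

test_that("full-canopy features are view-invariant while single views differ", {
  ## azimuth-dependent reflectance: each view sees a biased subset, the
  ## full-cloud mean does not depend on which views contributed
  set.seed(14)
  n <- 4000
  az <- runif(n, 0, 2 * pi)
  xyz <- cbind(cos(az), runif(n), sin(az))
  refl <- matrix(0.3 + 0.2 * sin(az), n, 1)
  cl <- MultispectralPointCloud(xyz, reflectance = refl, wavelengths = 500)

  quadrant <- findInterval(az, c(0, pi / 2, pi, 3 * pi / 2))
  aovFeatures <- vapply(1:4, function(q) {
    sub <- msplant3d:::.subsetCloud(cl, quadrant == q)
    unname(extractCanopyReflectance(sub, 500, source = paste0("AOV", q)))
  }, numeric(1))
  expect_gt(stats::sd(aovFeatures), 0.05)

  f1 <- extractCanopyReflectance(cl, 500)
  f2 <- extractCanopyReflectance(cl, 500)
  expect_identical(f1, f2)
  expect_equal(stats::sd(rep(unname(f1), 4)), 0)
})
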