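test_that("grayscale similarity D follows its closed form", {
  f <- mkTexturedImage(64, seed = 1)
  expect_equal(grayscaleSimilarity(f, f), 1)
  expect_equal(grayscaleSimilarity(matrix(0, 4, 4), matrix(255, 4, 4)), 0)
  expect_equal(grayscaleSimilarity(matrix(100, 1, 1) + 0, matrix(155, 1, 1) + 0),
               1 - 55 / 255)
  g <- mkTexturedImage(64, seed = 2)
  D <- grayscaleSimilarity(f, g)
  expect_gte(D, 0); expect_lte(D, 1)
  expect_error(grayscaleSimilarity(f, g[1:10, ]), class = "msp_dimension_error")
})

test_that("spectral overlap C counts reference coverage", {
  m <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 0), 3, 3)
  expect_equal(spectralOverlap(m, m), 100)
  expect_equal(spectralOverlap(m, 1 - m), 0)
  F2 <- matrix(0, 2, 2); F2[1:4] <- 1
  M2 <- matrix(c(1, 1, 1, 0), 2, 2)
  expect_equal(spectralOverlap(F2, M2), 75)
  expect_error(spectralOverlap(matrix(0, 2, 2), M2),
               class = "msp_degenerate_error")
})

test_that("hausdorffSet is the directed NN distance set, equal to brute force", {
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(hausdorffSet(A, A), rep(0, 10))
  expect_equal(hausdorffSet(rbind(c(0, 0, 0), c(1, 0, 0)),
                            matrix(c(0, 0, 0), 1, 3)), c(0, 1))

  set.seed(11)
  for (rep in 1:3) {
    RP <- matrix(rnorm(1500), 500, 3)
    MP <- matrix(rnorm(1500), 500, 3)
    d2 <- outer(rowSums(RP^2), rowSums(MP^2), "+") - 2 * tcrossprod(RP, MP)
    brute <- sqrt(pmax(apply(d2, 1, min), 0))
    expect_equal(hausdorffSet(RP, MP), brute, tolerance = 1e-12)
    ## not symmetric in general; max is the directed Hausdorff distance
    expect_false(isTRUE(all.equal(sort(hausdorffSet(RP, MP)),
                                  sort(hausdorffSet(MP, RP)))))
    expect_equal(max(hausdorffSet(RP, MP)), max(brute))
  }
  expect_error(hausdorffSet(matrix(0, 0, 3), A), class = "msp_degenerate_error")
})

test_that("hdStats bins distances per the fixed segment edges", {
  s <- hdStats(rep(0, 10))
  expect_equal(hdSummary(s), c(hd_avg = 0, hd_std = 0, hd_max = 0))
  expect_equal(segmentProportions(s), c(100, 0, 0, 0, 0))

  s <- hdStats(c(0.05, 0.2, 0.5, 0.8, 1.5))
  expect_equal(segmentProportions(s), rep(20, 5))
  expect_equal(s@hdMax, 1.5)
  ## population (divide-by-N) standard deviation
  d <- c(0.1, 0.4, 0.7)
  expect_equal(hdStats(d)@hdStd, sqrt(mean((d - mean(d))^2)))

  set.seed(2)
  expect_equal(sum(segmentProportions(hdStats(rexp(1000)))), 100)
  expect_error(hdStats(numeric()), class = "msp_degenerate_error")
})

test_that("published mean segment proportions give the published cumulatives", {
  ## printed per-segment means; the cumulative coverage below 0.6 and 1.0 cm
  ## follows from the binning arithmetic
  props <- c(34.98, 17.98, 21.52, 16.17, 9.35)
  ## realise a distance set with exactly these proportions and re-bin it
  mids <- c(0.05, 0.2, 0.45, 0.8, 1.5)
  d <- rep(mids, round(props * 100))
  s <- hdStats(d)
  expect_equal(segmentProportions(s), props, tolerance = 1e-10)
  expect_equal(sum(segmentProportions(s)[1:3]), 74.48, tolerance = 0.005)
  expect_equal(sum(segmentProportions(s)[1:4]), 90.65, tolerance = 0.005)
})

test_that("Kabsch alignment recovers exact rigid maps from landmarks", {
  set.seed(4)
  cloud <- matrix(rnorm(300), 100, 3)
  th <- 30 * pi / 180
  R <- msplant3d:::.Ry(th)
  t <- c(0.1, -0.2, 0.05)
  moved <- sweep(cloud %*% t(R), 2, t, "+")

  lm <- c(1, 25, 60, 80)
  al <- kabschAlign(cloud[lm, ], moved[lm, ])
  expect_equal(al$rmse, 0, tolerance = 1e-10)
  expect_equal(al$R, R, tolerance = 1e-10)

  ## reference in a rotated frame comes back after landmark alignment
  s <- evaluateReconstruction(moved, cloud,
                              pairs = list(recon = moved[lm, ],
                                           reference = cloud[lm, ]))
  expect_lt(s@hdAvg, 1e-6)

  collinear <- cbind(1:4, 0, 0)
  expect_error(kabschAlign(collinear, collinear %*% t(R)),
               class = "msp_alignment_error")
  expect_error(kabschAlign(cloud[1:2, ], moved[1:2, ]),
               class = "msp_alignment_error")
})

test_that("evaluateReconstruction with identical clouds gives zero stats", {
  set.seed(5)
  cl <- MultispectralPointCloud(matrix(rnorm(60), 20, 3))
  s <- evaluateReconstruction(cl, cl)
  expect_equal(unname(hdSummary(s)), c(0, 0, 0))
  expect_equal(segmentProportions(s)[1], 100)
})
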