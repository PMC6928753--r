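test_that("smoothSpectra preserves constants and interior mass, reduces noise", {
  wl <- seq(400, 700, length.out = 61)
  const <- SpectraMatrix(matrix(0.3, 2, 61), wl)
  expect_equal(reflectance(smoothSpectra(const)), matrix(0.3, 2, 61),
               tolerance = 1e-12)

  spike <- matrix(0, 1, 61); spike[1, 31] <- 1
  sm <- smoothSpectra(SpectraMatrix(spike, wl))
  expect_equal(sum(reflectance(sm)), 1, tolerance = 1e-6)   # mass conserved

  set.seed(6)
  noisy <- matrix(rnorm(61 * 20), 20, 61) + 1
  smn <- smoothSpectra(SpectraMatrix(pmax(noisy, 0), wl))
  v0 <- mean(apply(pmax(noisy, 0), 1, var))
  v1 <- mean(apply(reflectance(smn), 1, var))
  expect_lt(v1, v0)

  expect_error(smoothSpectra(const, window = 2), class = "msp_value_error")
  expect_error(smoothSpectra(const, window = 100), class = "msp_value_error")
})

test_that("interference-band removal maps 128 instrument bands to 122", {
  wl <- defaultWavelengthGrid()
  expect_equal(length(wl), 128L)
  sp <- SpectraMatrix(matrix(runif(128 * 4), 4, 128), wl)
  red <- removeInterferenceBands(sp)
  expect_equal(ncol(reflectance(red)), 122L)
  expect_false(any(interferenceBands() %in% wavelengths(red)))

  expect_identical(removeInterferenceBands(sp, numeric()), sp)
  ## asking again for a removed band is a lookup error
  expect_error(removeInterferenceBands(red, interferenceBands()[1]),
               class = "msp_lookup_error")
})

test_that("pcaWeights reports contributions and loading peaks", {
  set.seed(10)
  wl <- seq(400, 700, length.out = 80)
  ## rank-1 matrix: first component carries all variance
  scores <- rnorm(30)
  l1 <- dnorm(seq_len(80), 30, 4)
  r1 <- outer(scores, l1) + 1
  p1 <- pcaWeights(SpectraMatrix(r1, wl), nComponents = 3)
  expect_equal(p1$contributions[1], 100, tolerance = 1e-6)

  ## two orthogonal loading patterns: their peak positions are recovered
  l2 <- dnorm(seq_len(80), 60, 4)
  r2 <- outer(rnorm(40, sd = 3), l1) + outer(rnorm(40, sd = 1), l2) + 1
  p2 <- pcaWeights(SpectraMatrix(r2, wl), nComponents = 2)
  expect_true(all(diff(p2$contributions) <= 0))
  expect_lte(sum(p2$contributions), 100 + 1e-9)
  peakIdx <- match(p2$peakWavelengths, wl)
  expect_true(any(abs(peakIdx - 30) <= 2))
  expect_true(any(abs(peakIdx - 60) <= 2))

  expect_error(pcaWeights(SpectraMatrix(matrix(1, 10, 80), wl)),
               class = "msp_degenerate_error")
})

test_that("nutrient correlations are Pearson r with zero-variance flagging", {
  set.seed(11)
  wl <- seq(400, 700, length.out = 50)
  X <- matrix(rnorm(500 * 50), 500, 50) + 1
  X[, 7] <- 2   # zero variance
  sp <- SpectraMatrix(X, wl)

  r <- nutrientCorrelations(sp, X[, 3])
  expect_equal(unname(r[3]), 1)
  r2 <- nutrientCorrelations(sp, -X[, 3])
  expect_equal(unname(r2[3]), -1)
  expect_equal(unname(r[7]), 0)
  expect_true(attr(r, "zeroVariance")[7])

  yNull <- rnorm(500)
  rn <- nutrientCorrelations(sp, yNull)
  expect_lt(max(abs(rn[-7])), 0.15)

  expect_error(nutrientCorrelations(SpectraMatrix(X[1:2, ], wl), 1:2),
               class = "msp_value_error")
})

test_that("spectral autocorrelation matrix is a proper correlation matrix", {
  set.seed(12)
  wl <- seq(400, 700, length.out = 30)
  X <- matrix(rnorm(300), 10, 30) + 1
  X[, 30] <- X[, 1]
  ac <- spectralAutocorrelation(SpectraMatrix(X, wl))
  expect_equal(diag(ac), rep(1, 30))
  expect_lt(max(abs(ac - t(ac))), 1e-12)
  expect_equal(ac[1, 30], 1)
})

test_that("random frog concentrates probability on planted wavelengths", {
  ds <- makePlantedSignalSpectra(n = 200, seed = 1)
  sm <- removeInterferenceBands(ds$spectra)
  rf <- randomFrog(sm, ds$y, nIter = 1000, seed = 101)
  expect_true(all(rf >= 0 & rf <= 1))
  expect_identical(randomFrog(sm, ds$y, nIter = 1000, seed = 101), rf)

  top8 <- as.numeric(names(sort(rf, decreasing = TRUE)[1:8]))
  hits <- sum(vapply(ds$planted, function(p) any(abs(top8 - p) < 0.01),
                     logical(1)))
  expect_equal(hits, 5L)

  expect_error(randomFrog(sm, ds$y, nIter = 50), class = "msp_value_error")
})

test_that("random frog gives no confident selection on a pure-noise response", {
  ## under the null every subset scores alike, so the chain keeps moving and
  ## no band accumulates the high probabilities that planted signal bands
  ## reach (compare the > 0.7 planted probabilities above); residual
  ## occupancy fluctuation from chain autocorrelation is expected
  ds <- makePlantedSignalSpectra(n = 150, seed = 4)
  sm <- removeInterferenceBands(ds$spectra)
  set.seed(40)
  yNull <- rnorm(150)
  rf <- randomFrog(sm, yNull, nIter = 1000, seed = 41)
  expect_lt(max(rf), 0.3)
  expect_lt(mean(rf), 0.05)
})

test_that("selectWavelengths combines RF peaks, screens and supplements", {
  ds <- makePlantedSignalSpectra(n = 200, seed = 2)
  sm <- removeInterferenceBands(ds$spectra)
  wl <- wavelengths(sm)
  pca <- pcaWeights(sm)
  cc <- nutrientCorrelations(sm, ds$y)
  ac <- spectralAutocorrelation(sm)
  rf <- randomFrog(sm, ds$y, nIter = 1000, seed = 102)

  ## neutral screens: selection equals the admissible RF peaks
  rules0 <- list(adjacencyR = 0, minAbsCorrelation = 0, supplement = numeric())
  sel0 <- selectWavelengths(pca$peakWavelengths, cc, rf, ac, wl, rules0)
  peaks <- wl[msplant3d:::.localPeaks(rf)]
  expect_equal(wavelengths(sel0), sort(peaks))
  expect_true(all(sel0@provenance == "RF-peak"))

  ## planted bands survive the screens (the fixture's unsmoothed random
  ## fields have a short correlation length, so the adjacency gate is set
  ## to match it)
  sel <- selectWavelengths(pca$peakWavelengths, cc, rf, ac, wl,
                           list(adjacencyR = 0.5, minAbsCorrelation = 0.1,
                                nutrient = "N"))
  expect_true(all(vapply(ds$planted, function(p)
    any(abs(wavelengths(sel) - p) < 0.01), logical(1))))
  ## selection never returns a removed interference band
  expect_false(any(wavelengths(sel) %in% interferenceBands()))

  ## supplements are appended and flagged
  supp <- wl[5]
  sel2 <- selectWavelengths(pca$peakWavelengths, cc, rf, ac, wl,
                            list(minAbsCorrelation = 0.1, supplement = supp))
  expect_true(supp %in% wavelengths(sel2))
  expect_equal(sel2@provenance[wavelengths(sel2) == supp], "PCA-CC-supplement")
  expect_error(selectWavelengths(pca$peakWavelengths, cc, rf, ac, wl,
                                 list(supplement = 123.4)),
               class = "msp_lookup_error")
})

test_that("the published selection table round-trips as an I/O format", {
  ## published N-content selection used as a format fixture
  sel <- new("SelectionResult", nutrient = "N",
             wavelengths = c(451.6, 544.1, 585.7, 696.3, 739.0),
             provenance = c("RF-peak", "RF-peak", "RF-peak",
                            "PCA-CC-supplement", "RF-peak"))
  path <- tempfile(fileext = ".json")
  writeSelectionResult(sel, path)
  back <- readSelectionResult(path)
  expect_equal(wavelengths(back), wavelengths(sel))
  expect_equal(back@provenance, sel@provenance)
  expect_output(show(back), "696.3\\*")
})
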