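## Characteristic-wavelength selection for canopy nutrients: Gaussian
## smoothing, interference-band removal, PCA loading peaks, per-wavelength
## nutrient correlations, random-frog selection probabilities, and the
## combination rule producing the final wavelength set per nutrient.

#' Gaussian smoothing of spectra
#'
#' Per-curve 1-D Gaussian convolution with reflective boundary handling. The
#' kernel has standard deviation \code{window / 3} samples and support
#' \code{2 * window + 1}; a data window of 6 (the default) therefore gives a
#' sigma of 2 samples.
#'
#' @param spectra a [SpectraMatrix-class].
#' @param window odd-spirited width parameter, >= 3 and at most the band
#'   count.
#' @return smoothed [SpectraMatrix-class], same shape.
#' @export
smoothSpectra <- function(spectra, window = 6) {
  stopifnot(is(spectra, "SpectraMatrix"))
  p <- ncol(reflectance(spectra))
  if (window < 3) .mspStop("msp_value_error", "window must be >= 3")
  if (window > p)
    .mspStop("msp_value_error", "window larger than the band count")
  sigma <- window / 3
  h <- as.integer(window)
  k <- stats::dnorm(-h:h, sd = sigma); k <- k / sum(k)
  X <- reflectance(spectra)
  sm <- t(apply(X, 1, function(r) {
    padded <- c(r[h:1], r, r[p:(p - h + 1)])       # reflective padding
    stats::convolve(padded, rev(k), type = "filter")
  }))
  SpectraMatrix(sm, wavelengths(spectra), spectra@sampleIds)
}

#' Remove interference-affected wavelength bands
#'
#' Drops the listed wavelengths (default: the six bands affected by the
#' depth sensor's infrared emitter, see [interferenceBands()]); with the
#' default list a 128-band matrix becomes 122 bands.
#'
#' @param spectra a [SpectraMatrix-class].
#' @param bands wavelengths (nm) to drop; each must exist in the grid.
#' @return reduced [SpectraMatrix-class].
#' @export
removeInterferenceBands <- function(spectra, bands = interferenceBands()) {
  stopifnot(is(spectra, "SpectraMatrix"))
  if (!length(bands)) return(spectra)
  wl <- wavelengths(spectra)
  idx <- vapply(bands, function(b) {
    k <- which(abs(wl - b) < 1e-6)
    if (!length(k))
      .mspStop("msp_lookup_error", sprintf("wavelength %.2f nm not on the grid", b))
    k
  }, integer(1))
  SpectraMatrix(reflectance(spectra)[, -idx, drop = FALSE], wl[-idx],
                spectra@sampleIds)
}

## Local maxima of a vector (strictly greater than both neighbours).
.localPeaks <- function(v) {
  p <- length(v)
  if (p < 3) return(integer())
  which(v[2:(p - 1)] > v[1:(p - 2)] & v[2:(p - 1)] > v[3:p]) + 1L
}

#' PCA of spectra with loading-peak candidates
#'
#' PCA on mean-centred (not variance-scaled: reflectances share one unit)
#' spectra. Reports per-component explained-variance percentages, the
#' loading vectors, and the local extrema of the aggregated absolute
#' loadings (each component weighted by its contribution) as candidate
#' wavelengths.
#'
#' @param spectra a [SpectraMatrix-class].
#' @param nComponents number of components to keep (default 8).
#' @return list with \code{contributions} (percent, non-increasing),
#'   \code{cumulativeContribution}, \code{loadings} (wavelengths x
#'   components), \code{aggregate} (weighted absolute loadings) and
#'   \code{peakWavelengths} (nm).
#' @export
pcaWeights <- function(spectra, nComponents = 8L) {
  stopifnot(is(spectra, "SpectraMatrix"))
  X <- reflectance(spectra)
  if (nrow(X) < nComponents)
    .mspStop("msp_value_error", "need at least nComponents samples")
  if (all(apply(X, 2, stats::sd) < 1e-12))
    .mspStop("msp_degenerate_error", "zero-variance spectra matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(nComponents, length(pc$sdev))
  contrib <- 100 * pc$sdev[1:k]^2 / sum(pc$sdev^2)
  w <- contrib / sum(contrib)
  agg <- abs(pc$rotation[, 1:k, drop = FALSE]) %*% w
  wl <- wavelengths(spectra)
  list(contributions = contrib,
       cumulativeContribution = sum(contrib),
       loadings = pc$rotation[, 1:k, drop = FALSE],
       aggregate = as.numeric(agg),
       peakWavelengths = wl[.localPeaks(as.numeric(agg))])
}

#' Per-wavelength correlation with a nutrient
#'
#' Pearson correlation of each wavelength column with the nutrient values.
#' Zero-variance columns are recorded as r = 0 and flagged (attribute
#' \code{zeroVariance}) rather than propagating NaN.
#'
#' @param spectra a [SpectraMatrix-class].
#' @param y numeric nutrient values, one per sample (>= 3 samples).
#' @return numeric vector of correlations (one per wavelength) with
#'   attribute \code{zeroVariance}.
#' @export
nutrientCorrelations <- function(spectra, y) {
  stopifnot(is(spectra, "SpectraMatrix"))
  X <- reflectance(spectra)
  if (nrow(X) < 3L) .mspStop("msp_value_error", "need at least 3 samples")
  if (length(y) != nrow(X))
    .mspStop("msp_dimension_error", "one nutrient value per sample required")
  sds <- apply(X, 2, stats::sd)
  zero <- sds < 1e-12
  r <- numeric(ncol(X))
  if (any(!zero)) r[!zero] <- as.numeric(stats::cor(X[, !zero, drop = FALSE], y))
  structure(r, zeroVariance = zero)
}

#' Wavelength-by-wavelength autocorrelation matrix
#'
#' @param spectra a [SpectraMatrix-class].
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   columns yield 0 off-diagonal.
#' @export
spectralAutocorrelation <- function(spectra) {
  stopifnot(is(spectra, "SpectraMatrix"))
  X <- reflectance(spectra)
  suppressWarnings(ac <- stats::cor(X))
  ac[!is.finite(ac)] <- 0
  diag(ac) <- 1
  ac
}

## ---- PLS (SIMPLS) inner model for random frog ------------------------------

## Minimal SIMPLS returning regression coefficients for 1..A latent
## variables. X: n x p, y: n. Returns p x A coefficient matrix (on centred
## data) plus the centres.
.simpls <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  A <- min(A, p, n - 1L)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx); yc <- y - my
  S <- crossprod(Xc, yc)              # p x 1
  R <- matrix(0, p, A); V <- matrix(0, p, A)
  Tm <- matrix(0, n, A); B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    r <- S
    t <- Xc %*% r
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) { A <- a - 1L; break }
    t <- t / nt; r <- r / nt
    pvec <- crossprod(Xc, t)
    v <- pvec
    if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], pvec)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) { A <- a - 1L; break }
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v; Tm[, a] <- t
    q <- crossprod(Tm[, 1:a, drop = FALSE], yc)
    B[, a] <- R[, 1:a, drop = FALSE] %*% q
  }
  if (A < 1L) return(NULL)
  list(B = B[, seq_len(A), drop = FALSE], mx = mx, my = my, A = A)
}

## Cross-validated RMSE of a PLS model on variable subset `vars`, choosing
## the best number of latent variables up to nLV. `folds` is a fixed integer
## assignment so all subsets are scored on identical splits.
.plsCVRMSE <- function(X, y, vars, nLV, folds) {
  Xs <- X[, vars, drop = FALSE]
  k <- max(folds)
  Amax <- min(nLV, length(vars))
  press <- matrix(0, 1, Amax)
  cnt <- 0
  sse <- rep(0, Amax)
  for (f in seq_len(k)) {
    te <- folds == f
    fit <- .simpls(Xs[!te, , drop = FALSE], y[!te], Amax)
    if (is.null(fit)) return(list(rmse = Inf, nLV = 0L))
    Xt <- sweep(Xs[te, , drop = FALSE], 2, fit$mx)
    pred <- Xt %*% fit$B + fit$my          # n_te x A
    err <- (pred - y[te])^2
    sse[seq_len(fit$A)] <- sse[seq_len(fit$A)] + colSums(err)
    if (fit$A < Amax) sse[(fit$A + 1):Amax] <- Inf
    cnt <- cnt + sum(te)
  }
  rmse <- sqrt(sse / cnt)
  ## score at the full model depth: extra noise variables then cost CV error
  ## instead of being absorbed by a smaller latent space
  a <- length(rmse)
  list(rmse = rmse[a], nLV = a)
}

## Mean absolute PLS regression coefficient per variable (for ranking).
.plsCoefRank <- function(X, y, vars, nLV) {
  fit <- .simpls(X[, vars, drop = FALSE], y, min(nLV, length(vars)))
  if (is.null(fit)) return(rep(0, length(vars)))
  abs(fit$B[, ncol(fit$B)])
}

#' Random-frog wavelength selection probabilities
#'
#' Iterative reversible-jump-style search over wavelength subsets with a
#' partial-least-squares inner model. Each iteration proposes a subset whose
#' size is drawn from a normal around the current size (spread
#' \code{varFactor} times the size); shrinking keeps the variables with the
#' largest absolute PLS coefficients, growing adds a random pool from the
#' complement and keeps the best by the same ranking. The candidate is
#' accepted if its cross-validated RMSE improves, otherwise with probability
#' \code{eta * RMSE / RMSE*}. The selection probability of a wavelength is
#' its selection count over the iterations.
#'
#' @param spectra a [SpectraMatrix-class].
#' @param y nutrient values, one per sample.
#' @param nIter iterations, >= 100 (default 1000).
#' @param q0 initial subset size (default 5).
#' @param varFactor proposal spread factor (default 0.3).
#' @param nLV maximum PLS latent variables (default 5).
#' @param eta acceptance factor for worse candidates (default 0.1).
#' @param nFolds cross-validation folds (default 5).
#' @param seed integer seed; the run is deterministic given the seed.
#' @return numeric vector of selection probabilities in [0, 1], one per
#'   wavelength, named by wavelength.
#' @export
randomFrog <- function(spectra, y, nIter = 1000L, q0 = 5L, varFactor = 0.3,
                       nLV = 5L, eta = 0.1, nFolds = 5L, seed = 1L) {
  stopifnot(is(spectra, "SpectraMatrix"))
  if (nIter < 100L)
    .mspStop("msp_value_error", "nIter below the burn-in length (100)")
  X <- reflectance(spectra)
  p <- ncol(X); n <- nrow(X)
  if (length(y) != n)
    .mspStop("msp_dimension_error", "one response value per sample required")
  .withSeed(seed, {
    V <- sample.int(p, min(q0, p))
    counts <- numeric(p)
    for (it in seq_len(nIter)) {
      ## fresh folds each iteration, shared by current and candidate: the
      ## comparison stays fair while no subset can sit on a lucky fixed split
      folds <- sample(rep(seq_len(nFolds), length.out = n))
      q <- length(V)
      qs <- round(stats::rnorm(1, q, varFactor * q))
      qs <- max(1L, min(p, qs))
      if (qs == q) {
        ## exchange move: swap one member for a random outsider (keeps the
        ## chain mixing when the size proposal does not change q)
        comp <- setdiff(seq_len(p), V)
        Vs <- V
        if (length(comp)) Vs[sample.int(q, 1)] <- sample(comp, 1)
      } else if (qs < q) {
        rank <- .plsCoefRank(X, y, V, nLV)
        Vs <- V[order(rank, decreasing = TRUE)[seq_len(qs)]]
      } else {
        comp <- setdiff(seq_len(p), V)
        extra <- sample(comp, min(length(comp), 3L * (qs - q)))
        pool <- c(V, extra)
        rank <- .plsCoefRank(X, y, pool, nLV)
        Vs <- pool[order(rank, decreasing = TRUE)[seq_len(min(qs, length(pool)))]]
      }
      scoreV <- .plsCVRMSE(X, y, V, nLV, folds)$rmse
      scoreVs <- .plsCVRMSE(X, y, Vs, nLV, folds)$rmse
      accept <- scoreVs <= scoreV ||
        stats::runif(1) < eta * scoreV / scoreVs
      if (accept) V <- Vs
      counts[V] <- counts[V] + 1
    }
    stats::setNames(counts / nIter, sprintf("%.2f", wavelengths(spectra)))
  })
}

#' Combine PCA, correlation and random-frog evidence into a wavelength set
#'
#' Takes the local peaks of the random-frog selection probability that sit
#' in regions where adjacent wavelengths are highly correlated (adjacency
#' screen), drops peaks that fail both the nutrient-correlation screen and
#' the PCA-peak proximity screen, and appends any PCA-CC supplement
#' wavelengths (flagged as such in the provenance).
#'
#' @param pcaPeaks numeric, PCA loading-peak wavelengths (nm), e.g. from
#'   [pcaWeights()]\code{$peakWavelengths}.
#' @param correlations per-wavelength nutrient correlations (from
#'   [nutrientCorrelations()]), aligned with \code{wavelengthGrid}.
#' @param rfProbs per-wavelength random-frog probabilities (from
#'   [randomFrog()]), same grid.
#' @param autocorr wavelength autocorrelation matrix (from
#'   [spectralAutocorrelation()]).
#' @param wavelengthGrid the common wavelength grid, nm.
#' @param rules list of screening rules: \code{adjacencyR} (minimum
#'   neighbour correlation, default 0.9), \code{minAbsCorrelation} (minimum
#'   |r| for a peak to survive on correlation evidence, default 0.5),
#'   \code{pcaTolNm} (distance to a PCA peak that counts as PCA support,
#'   default 10), \code{supplement} (wavelengths added on PCA-CC evidence,
#'   default none), \code{nutrient} (label, default "N").
#' @return A [SelectionResult-class].
#' @export
selectWavelengths <- function(pcaPeaks, correlations, rfProbs, autocorr,
                              wavelengthGrid, rules = list()) {
  r <- utils::modifyList(list(adjacencyR = 0.9, minAbsCorrelation = 0.5,
                              pcaTolNm = 10, supplement = numeric(),
                              nutrient = "N"), rules)
  p <- length(wavelengthGrid)
  stopifnot(length(correlations) == p, length(rfProbs) == p)
  peaks <- .localPeaks(rfProbs)
  ## adjacency screen: both neighbours must be strongly correlated bands
  peaks <- peaks[vapply(peaks, function(i)
    abs(autocorr[i, i - 1]) >= r$adjacencyR &&
      abs(autocorr[i, i + 1]) >= r$adjacencyR, logical(1))]
  ## PCA / correlation screen
  keep <- vapply(peaks, function(i) {
    corOK <- abs(correlations[i]) >= r$minAbsCorrelation
    pcaOK <- length(pcaPeaks) &&
      min(abs(pcaPeaks - wavelengthGrid[i])) <= r$pcaTolNm
    corOK || pcaOK
  }, logical(1))
  sel <- wavelengthGrid[peaks[keep]]
  prov <- rep("RF-peak", length(sel))
  for (s in r$supplement) {
    if (!any(abs(wavelengthGrid - s) < 1e-6))
      .mspStop("msp_lookup_error",
               sprintf("supplement wavelength %.2f nm not on the grid", s))
    if (!any(abs(sel - s) < 1e-6)) {
      sel <- c(sel, s); prov <- c(prov, "PCA-CC-supplement")
    }
  }
  if (!length(sel))
    .mspStop("msp_empty_selection_error", "no candidate wavelengths survived")
  o <- order(sel)
  new("SelectionResult", nutrient = r$nutrient, wavelengths = sel[o],
      provenance = prov[o])
}

#' Full characteristic-wavelength selection pipeline for one nutrient
#'
#' Convenience wrapper chaining [smoothSpectra()],
#' [removeInterferenceBands()], [pcaWeights()], [nutrientCorrelations()],
#' [spectralAutocorrelation()], [randomFrog()] and [selectWavelengths()].
#'
#' @param spectra a [SpectraMatrix-class] (raw instrument grid).
#' @param y nutrient values, one per sample.
#' @param nutrient label for the result.
#' @param interference wavelengths to drop (default [interferenceBands()]
#'   when present on the grid, none otherwise).
#' @param rfIter random-frog iterations.
#' @param seed integer seed.
#' @param rules extra screening rules passed to [selectWavelengths()].
#' @return A [SelectionResult-class].
#' @export
selectCharacteristicWavelengths <- function(spectra, y, nutrient = "N",
                                            interference = NULL,
                                            rfIter = 1000L, seed = 1L,
                                            rules = list()) {
  sm <- smoothSpectra(spectra)
  if (is.null(interference)) {
    interference <- intersect(interferenceBands(), wavelengths(sm))
  }
  sm <- removeInterferenceBands(sm, interference)
  pca <- pcaWeights(sm)
  cc <- nutrientCorrelations(sm, y)
  ac <- spectralAutocorrelation(sm)
  rf <- randomFrog(sm, y, nIter = rfIter, seed = seed)
  rules$nutrient <- nutrient
  selectWavelengths(pca$peakWavelengths, cc, rf, ac, wavelengths(sm), rules)
}
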