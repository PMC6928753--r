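## NPK regression models (back-propagation neural network, epsilon-SVR,
## Gaussian-process regression) on characteristic-band canopy reflectance,
## model evaluation (Rc2/Rp2/RMSEC/RMSEP/RE), and the wet-chemistry
## mass-fraction formulas for the reference measurements.

#' Mean canopy reflectance feature vector from a point cloud
#'
#' Per requested wavelength, the mean reflectance over points whose
#' reflectance is valid at that band (invalid points are excluded from the
#' mean, never counted as zero).
#'
#' @param cloud a [MultispectralPointCloud-class] with reflectance.
#' @param wl wavelengths to extract, nm; each must be carried by the cloud.
#' @param source label recorded on the result (e.g. "3DROI", "AOV1").
#' @return named numeric feature vector with attribute \code{source}.
#' @export
extractCanopyReflectance <- function(cloud, wl = wavelengths(cloud),
                                     source = "3DROI") {
  stopifnot(is(cloud, "MultispectralPointCloud"))
  if (!length(cloud@reflectance))
    .mspStop("msp_value_error", "cloud carries no reflectance")
  idx <- vapply(wl, function(w) {
    k <- which(abs(wavelengths(cloud) - w) < 1e-6)
    if (!length(k))
      .mspStop("msp_lookup_error", sprintf("wavelength %.2f nm absent", w))
    k
  }, integer(1))
  out <- vapply(idx, function(k) {
    v <- reflectance(cloud)[reflectanceValid(cloud)[, k], k]
    if (!length(v))
      .mspStop("msp_value_error", "no valid reflectance points for a band")
    mean(v)
  }, numeric(1))
  structure(stats::setNames(out, sprintf("%.2f", wl)), source = source)
}

## ---- back-propagation neural network ---------------------------------------

#' Fit a back-propagation neural network regression
#'
#' Three-layer feed-forward network: 15 (default) hidden units with tanh
#' activation and a linear output, trained on standardised inputs/outputs by
#' quasi-Newton (BFGS) optimisation of the mean-squared error with seeded
#' weight initialisation. Training stops at \code{maxit} epochs or when the
#' standardised MSE reaches \code{goal}.
#'
#' @param X n x p feature matrix.
#' @param y numeric response.
#' @param hidden hidden-layer size (default 15).
#' @param maxit maximum optimisation iterations (default 500).
#' @param goal target standardised MSE (default 1e-4).
#' @param decay L2 weight penalty (default 1e-6, numerical stabiliser).
#' @param seed integer seed for the weight initialisation.
#' @return object of class "bpannModel" with a [predict][stats::predict]
#'   method.
#' @export
fitBPANN <- function(X, y, hidden = 15L, maxit = 500L, goal = 1e-4,
                     decay = 1e-6, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) .mspStop("msp_value_error", "NA in training data")
  if (nrow(X) < 2L) .mspStop("msp_value_error", "need >= 2 samples")
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd); sx[sx < 1e-12] <- 1
  my <- mean(y); sy <- stats::sd(y); if (!is.finite(sy) || sy < 1e-12) sy <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  ys <- (y - my) / sy
  h <- as.integer(hidden)
  nw <- h * p + h + h + 1
  unpack <- function(w) list(
    W1 = matrix(w[seq_len(h * p)], h, p),
    b1 = w[h * p + seq_len(h)],
    w2 = w[h * p + h + seq_len(h)],
    b2 = w[nw])
  fwd <- function(par) {
    Z <- tanh(Xs %*% t(par$W1) + matrix(par$b1, n, h, byrow = TRUE))
    list(Z = Z, pred = as.numeric(Z %*% par$w2 + par$b2))
  }
  loss <- function(w) {
    par <- unpack(w); f <- fwd(par)
    mean((f$pred - ys)^2) + decay * sum(w^2)
  }
  grad <- function(w) {
    par <- unpack(w); f <- fwd(par)
    e <- 2 * (f$pred - ys) / n                   # d loss / d pred
    gw2 <- as.numeric(crossprod(f$Z, e))
    gb2 <- sum(e)
    D <- (e %o% par$w2) * (1 - f$Z^2)            # n x h
    gW1 <- crossprod(D, Xs)                      # h x p
    gb1 <- colSums(D)
    c(as.numeric(gW1), gb1, gw2, gb2) + 2 * decay * w
  }
  w <- .withSeed(seed, stats::rnorm(nw, 0, 0.5 / sqrt(p + 1)))
  it <- 0L
  while (it < maxit) {
    chunk <- min(100L, maxit - it)
    opt <- stats::optim(w, loss, grad, method = "BFGS",
                        control = list(maxit = chunk, reltol = 1e-12))
    w <- opt$par; it <- it + chunk
    if (opt$value <= goal || opt$convergence == 0) break
  }
  structure(list(w = unpack(w), mx = mx, sx = sx, my = my, sy = sy,
                 hidden = h, mse = loss(w)),
            class = "bpannModel")
}

#' @export
predict.bpannModel <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$mx), 2, object$sx, "/")
  Z <- tanh(Xs %*% t(object$w$W1) +
              matrix(object$w$b1, nrow(Xs), object$hidden, byrow = TRUE))
  as.numeric(Z %*% object$w$w2 + object$w$b2) * object$sy + object$my
}

## ---- epsilon-SVR ------------------------------------------------------------

#' Fit an epsilon support-vector regression with RBF kernel
#'
#' Gaussian kernel with the kernel scale expressed as in the original
#' modelling toolbox (gamma = 1 / (2 * kernelScale^2)); inputs are
#' standardised. "Automatic" box constraint and epsilon follow the
#' interquartile-range rule: box = iqr(y) / 1.349 (a robust estimate of the
#' response standard deviation), epsilon = box / 10.
#'
#' @param X n x p feature matrix.
#' @param y numeric response.
#' @param kernelScale RBF kernel scale (default 0.56, the fine-Gaussian
#'   preset); \code{"auto"} uses the median pairwise Euclidean distance of
#'   the standardised features.
#' @param cost box constraint; NULL (default) = automatic.
#' @param epsilon tube width; NULL (default) = automatic.
#' @return object of class "svmrModel".
#' @export
fitSVMR <- function(X, y, kernelScale = 0.56, cost = NULL, epsilon = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) .mspStop("msp_value_error", "NA in training data")
  if (identical(kernelScale, "auto")) {
    Xs <- scale(X); Xs[is.na(Xs)] <- 0
    kernelScale <- max(stats::median(stats::dist(Xs)), 1e-6)
  }
  ## "automatic" box/epsilon follow the iqr(y)/1.349 rule in raw response
  ## units; the svm backend standardises y internally, so both are expressed
  ## relative to sd(y) here (a Gaussian response gives cost 1, epsilon 0.1)
  iqr <- stats::IQR(y); sy <- stats::sd(y)
  if (!is.finite(sy) || sy < 1e-12) sy <- 1
  if (is.null(cost)) cost <- max(iqr / 1.349 / sy, 1e-3)
  if (is.null(epsilon)) epsilon <- max(iqr / 13.49 / sy, 1e-4)
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    gamma = 1 / (2 * kernelScale^2), cost = cost,
                    epsilon = epsilon, scale = TRUE)
  structure(list(fit = fit), class = "svmrModel")
}

#' @export
predict.svmrModel <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, as.matrix(newdata)))
}

## ---- Gaussian-process regression --------------------------------------------

.rqKernel <- function(D2, sf2, ell, alpha)
  sf2 * (1 + D2 / (2 * alpha * ell^2))^(-alpha)

.sqDist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
}

#' Fit a Gaussian-process regression with rational-quadratic kernel
#'
#' Constant (mean) basis, isotropic rational-quadratic kernel
#' \eqn{k(r) = \sigma_f^2 (1 + r^2 / (2\alpha \ell^2))^{-\alpha}} plus a
#' noise term; inputs and response are standardised and the constant mean is
#' absorbed by centring. Hyperparameters (length scale, signal variance,
#' noise variance, alpha) are optimised by maximising the log marginal
#' likelihood from several seeded restarts; Cholesky failures escalate the
#' jitter before giving up.
#'
#' @param X n x p feature matrix.
#' @param y numeric response.
#' @param nRestarts optimiser restarts (default 3).
#' @param seed integer seed for the restarts.
#' @return object of class "gprModel".
#' @export
fitGPR <- function(X, y, nRestarts = 3L, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) .mspStop("msp_value_error", "NA in training data")
  n <- nrow(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd); sx[sx < 1e-12] <- 1
  my <- mean(y); sy <- stats::sd(y); if (!is.finite(sy) || sy < 1e-12) sy <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  ys <- (y - my) / sy
  D2 <- .sqDist(Xs, Xs)
  negLogLik <- function(theta) {
    ell <- exp(theta[1]); sf2 <- exp(theta[2])
    sn2 <- exp(theta[3]); alpha <- exp(theta[4])
    K <- .rqKernel(D2, sf2, ell, alpha) + diag(sn2 + 1e-10, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), ys))
    0.5 * sum(ys * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  starts <- .withSeed(seed, lapply(seq_len(nRestarts), function(k)
    c(log(stats::runif(1, 0.5, 3)), log(stats::runif(1, 0.5, 2)),
      log(stats::runif(1, 1e-4, 1e-1)), log(stats::runif(1, 0.5, 4)))))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, negLogLik, method = "L-BFGS-B",
                   lower = log(c(1e-2, 1e-4, 1e-8, 1e-2)),
                   upper = log(c(1e3, 1e3, 1e2, 1e3))),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) .mspStop("msp_numeric_error", "GPR optimisation failed")
  th <- best$par
  ell <- exp(th[1]); sf2 <- exp(th[2]); sn2 <- exp(th[3]); alpha <- exp(th[4])
  K <- .rqKernel(D2, sf2, ell, alpha) + diag(sn2, n)
  L <- NULL
  for (jit in c(1e-10, 1e-8, 1e-6, 1e-4)) {
    L <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L))
    .mspStop("msp_numeric_error", "kernel matrix not positive definite")
  a <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(Xs = Xs, L = L, a = a, ell = ell, sf2 = sf2, sn2 = sn2,
                 alpha = alpha, mx = mx, sx = sx, my = my, sy = sy),
            class = "gprModel")
}

#' @param se.fit if TRUE, also return the posterior standard deviation.
#' @rdname fitGPR
#' @export
predict.gprModel <- function(object, newdata, se.fit = FALSE, ...) {
  Xn <- sweep(sweep(as.matrix(newdata), 2, object$mx), 2, object$sx, "/")
  Ks <- .rqKernel(.sqDist(Xn, object$Xs), object$sf2, object$ell, object$alpha)
  mu <- as.numeric(Ks %*% object$a) * object$sy + object$my
  if (!se.fit) return(mu)
  v <- forwardsolve(t(object$L), t(Ks))
  var <- pmax(object$sf2 - colSums(v^2), 0) * object$sy^2
  list(fit = mu, se.fit = sqrt(var))
}

## ---- evaluation -------------------------------------------------------------

#' Evaluate a regression model on calibration and prediction sets
#'
#' Rc2 and Rp2 are the squared Pearson correlations between measured and
#' predicted values on the calibration and prediction sets (matching a
#' measured-vs-predicted correlation analysis; set
#' \code{r2 = "variance"} for the 1 - SSE/SST convention). RMSEC/RMSEP are
#' root-mean-square residuals on each set; RE is the mean absolute relative
#' error over the prediction set, in percent. Constant predictions leave the
#' correlation-based R2 undefined: it is returned as NA with attribute
#' \code{undefinedR2}.
#'
#' @param model fitted model with a \code{predict} method.
#' @param Xc,yc calibration set.
#' @param Xp,yp prediction set (disjoint from calibration).
#' @param r2 "correlation" (default) or "variance".
#' @return one-row data.frame: Rc2, RMSEC, Rp2, RMSEP, RE.
#' @export
evaluateModel <- function(model, Xc, yc, Xp, yp, r2 = c("correlation", "variance")) {
  r2 <- match.arg(r2)
  pc <- stats::predict(model, Xc)
  pp <- stats::predict(model, Xp)
  if (any(yp == 0))
    .mspStop("msp_value_error", "relative error undefined for y = 0")
  r2fun <- function(obs, pred) {
    if (r2 == "variance") return(1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
    if (stats::sd(pred) < 1e-12 || stats::sd(obs) < 1e-12) return(NA_real_)
    stats::cor(obs, pred)^2
  }
  out <- data.frame(
    Rc2 = r2fun(yc, pc), RMSEC = sqrt(mean((pc - yc)^2)),
    Rp2 = r2fun(yp, pp), RMSEP = sqrt(mean((pp - yp)^2)),
    RE = mean(abs(pp - yp) / yp) * 100)
  attr(out, "undefinedR2") <- is.na(out$Rc2) || is.na(out$Rp2)
  out
}

#' Calibration/prediction split
#'
#' Seeded shuffle into a calibration and a prediction set (default 42/18,
#' the modelling/verification split used with 60 samples).
#'
#' @param n sample count.
#' @param nCalib calibration size (default 42).
#' @param seed integer seed.
#' @return list with integer vectors \code{calib} and \code{pred}.
#' @export
calibrationSplit <- function(n, nCalib = 42L, seed = 1L) {
  if (nCalib >= n) .mspStop("msp_value_error", "nCalib must be < n")
  .withSeed(seed, {
    idx <- sample.int(n)
    list(calib = sort(idx[seq_len(nCalib)]), pred = sort(idx[-seq_len(nCalib)]))
  })
}

#' Fit and evaluate the full nutrient x model x input grid
#'
#' For every nutrient, every input source (e.g. AOV1..AOV4 and 3DROI) and
#' every modelling approach (BPANN, SVMR, GPR), fits on the calibration
#' split and evaluates on the prediction split, emitting one row per
#' combination (3 x 5 x 3 = 45 rows for the full design).
#'
#' @param features named list: source -> (feature matrix, samples x bands,
#'   or named list nutrient -> matrix when feature sets differ by nutrient).
#' @param npk data.frame of measured nutrient values (columns =
#'   \code{nutrients}).
#' @param nutrients nutrient columns to model (default N, P, K).
#' @param methods subset of c("BPANN", "SVMR", "GPR").
#' @param split list with \code{calib} and \code{pred} indices (default:
#'   [calibrationSplit()] of the sample count).
#' @param seed integer seed for the seeded learners.
#' @return data.frame with columns Nutrient, Input, Model, Rc2, RMSEC, Rp2,
#'   RMSEP, RE.
#' @export
runModelMatrix <- function(features, npk, nutrients = c("N", "P", "K"),
                           methods = c("BPANN", "SVMR", "GPR"),
                           split = NULL, seed = 1L) {
  n <- nrow(npk)
  if (is.null(split)) split <- calibrationSplit(n, seed = seed)
  fitters <- list(
    BPANN = function(X, y) fitBPANN(X, y, seed = seed),
    SVMR = function(X, y) fitSVMR(X, y),
    GPR = function(X, y) fitGPR(X, y, seed = seed))
  rows <- list()
  for (nu in nutrients) for (src in names(features)) {
    Xall <- features[[src]]
    if (is.list(Xall) && !is.matrix(Xall)) Xall <- Xall[[nu]]
    Xall <- as.matrix(Xall)
    if (nrow(Xall) != n)
      .mspStop("msp_dimension_error",
               "feature rows must match the nutrient table")
    y <- npk[[nu]]
    for (meth in methods) {
      fit <- fitters[[meth]](Xall[split$calib, , drop = FALSE], y[split$calib])
      ev <- evaluateModel(fit, Xall[split$calib, , drop = FALSE], y[split$calib],
                          Xall[split$pred, , drop = FALSE], y[split$pred])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(Nutrient = nu, Input = src, Model = meth), ev)
    }
  }
  do.call(rbind, rows)
}

## ---- wet-chemistry mass fractions -------------------------------------------

#' Wet-chemistry mass fractions of N, P and K
#'
#' Reference-method formulas expressing nutrient content as a mass fraction
#' in g/100 g of dried sample.
#'
#' Nitrogen (Kjeldahl titration):
#' \deqn{w_1 = \frac{(V_2 - V_0) \times c \times 0.0140}{m (V_1 / V)} \times 100}
#'
#' @param V2 acid volume consumed by the sample, mL.
#' @param V0 acid volume consumed by the blank, mL.
#' @param c concentration of the acid standard titration solution, mol/L.
#' @param V1 volume of test liquid taken for distillation, mL.
#' @param V total volume of the test liquid, mL.
#' @param m sample mass, g.
#' @return mass fraction, g/100 g.
#' @export
nitrogenMassFraction <- function(V2, V0, c, V1, V, m) {
  if (any(m <= 0) || any(V1 <= 0) || any(V <= 0))
    .mspStop("msp_value_error", "m, V1 and V must be positive")
  (V2 - V0) * c * 0.0140 / (m * (V1 / V)) * 100
}

#' Phosphorus mass fraction (molybdenum-antimony spectrophotometry)
#'
#' \deqn{w_2 = \rho \frac{V}{m} \frac{V_2}{V_1} \times 10^{-4}}
#'
#' @param rho P mass concentration in the test liquid, mg/L.
#' @param V volume of the test liquid, mL.
#' @param V1 dispensed volume of the test liquid, mL.
#' @param V2 volume of the colour solution, mL.
#' @param m sample mass, g.
#' @return mass fraction, g/100 g.
#' @export
phosphorusMassFraction <- function(rho, V, V1, V2, m) {
  if (any(m <= 0) || any(V1 <= 0))
    .mspStop("msp_value_error", "m and V1 must be positive")
  rho * V / m * V2 / V1 * 1e-4
}

#' Potassium mass fraction (flame atomic absorption)
#'
#' \deqn{w_3 = (\rho - \rho_0) \frac{V}{m} \frac{V_2}{V_1} \times 10^{-4}}
#'
#' @param rho K mass concentration in the test liquid, mg/L.
#' @param rho0 K mass concentration in the reagent blank, mg/L.
#' @inheritParams phosphorusMassFraction
#' @return mass fraction, g/100 g.
#' @export
potassiumMassFraction <- function(rho, rho0, V, V1, V2, m) {
  if (any(m <= 0) || any(V1 <= 0))
    .mspStop("msp_value_error", "m and V1 must be positive")
  (rho - rho0) * V / m * V2 / V1 * 1e-4
}
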