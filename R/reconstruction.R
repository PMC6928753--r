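## RGB-D back-projection, axis-based rough registration of turntable views,
## and point-to-point ICP refinement, chained sequentially over views to
## produce one multispectral point cloud.

#' Depth-camera intrinsics
#'
#' @param cx,cy principal point, pixels (x = column, y = row, 0-based).
#' @param fx,fy focal lengths, pixels (> 0).
#' @return validated list of class "CameraIntrinsics".
#' @export
cameraIntrinsics <- function(cx, cy, fx, fy) {
  if (fx <= 0 || fy <= 0) .mspStop("msp_value_error", "focal lengths must be > 0")
  structure(list(cx = cx, cy = cy, fx = fx, fy = fy),
            class = "CameraIntrinsics")
}

#' Back-project a depth image to a point cloud
#'
#' Pinhole model, pixel (i = column, j = row, 0-based), depth in mm
#' (0 = missing, produces no point):
#' \deqn{x = (i - c_x) z / f_x, \quad y = -(j - c_y) z / f_y, \quad z = Depth(i,j)/1000}
#' so +y points up in the camera frame. Aligned per-pixel attributes (RGB,
#' registered reflectance from [stackRegistered()]) are copied onto the
#' points; spectral pixels outside the registered cube give points whose
#' reflectance is marked invalid, not zero.
#'
#' @param depth rows x cols numeric matrix, mm, 0 = invalid.
#' @param intr a [cameraIntrinsics()] object.
#' @param attrs optional aligned channel stack (from [stackRegistered()]) or
#'   NULL.
#' @return A [MultispectralPointCloud-class].
#' @export
depthToCloud <- function(depth, intr, attrs = NULL) {
  stopifnot(inherits(intr, "CameraIntrinsics"))
  if (!is.matrix(depth) || any(depth < 0, na.rm = TRUE))
    .mspStop("msp_value_error", "depth must be a non-negative matrix (mm)")
  sel <- which(is.finite(depth) & depth > 0)
  if (!length(sel)) .mspStop("msp_empty_cloud_error", "no valid depth pixels")
  m <- nrow(depth)
  j <- (sel - 1) %% m          # 0-based row
  i <- (sel - 1) %/% m         # 0-based col
  z <- depth[sel] / 1000
  xyz <- cbind((i - intr$cx) * z / intr$fx,
               -(j - intr$cy) * z / intr$fy,
               z)
  rgb <- NULL; refl <- NULL; rv <- NULL; wl <- numeric()
  if (!is.null(attrs)) {
    chan <- attr(attrs, "channels")
    if (!identical(dim(attrs)[1:2], dim(depth)))
      .mspStop("msp_dimension_error", "attrs must be aligned to depth pixels")
    rgbIdx <- match(c("R", "G", "B"), chan)
    if (!anyNA(rgbIdx))
      rgb <- cbind(attrs[, , rgbIdx[1]][sel], attrs[, , rgbIdx[2]][sel],
                   attrs[, , rgbIdx[3]][sel])
    rIdx <- grep("^refl_", chan)
    if (length(rIdx)) {
      wl <- attr(attrs, "wavelengths")
      refl <- vapply(rIdx, function(k) attrs[, , k][sel], numeric(length(sel)))
      refl <- matrix(refl, ncol = length(rIdx))
      msk <- attr(attrs, "spectralMask")
      rv <- if (is.null(msk)) is.finite(refl) else
        matrix(rep(msk[sel], length(rIdx)), ncol = length(rIdx))
      refl[!rv] <- NA_real_
    }
  }
  MultispectralPointCloud(xyz, rgb = rgb, reflectance = refl, reflValid = rv,
                          wavelengths = wl %||% numeric())
}

#' Axis-aligned box filter (region of interest)
#'
#' Retains points inside the closed box; all per-point attributes follow.
#'
#' @param cloud a [MultispectralPointCloud-class].
#' @param bounds list with numeric(3) \code{min} and \code{max} (m),
#'   min < max per axis.
#' @return filtered cloud (possibly empty).
#' @export
roiFilter <- function(cloud, bounds) {
  stopifnot(is(cloud, "MultispectralPointCloud"))
  if (any(bounds$min >= bounds$max))
    .mspStop("msp_value_error", "ROI box needs min < max per axis")
  xyz <- coords(cloud)
  keep <- xyz[, 1] >= bounds$min[1] & xyz[, 1] <= bounds$max[1] &
          xyz[, 2] >= bounds$min[2] & xyz[, 2] <= bounds$max[2] &
          xyz[, 3] >= bounds$min[3] & xyz[, 3] <= bounds$max[3]
  .subsetCloud(cloud, keep)
}

.subsetCloud <- function(cloud, keep) {
  MultispectralPointCloud(
    coords(cloud)[keep, , drop = FALSE],
    rgb = if (nrow(cloud@rgb)) cloud@rgb[keep, , drop = FALSE],
    reflectance = if (length(cloud@reflectance))
      cloud@reflectance[keep, , drop = FALSE],
    reflValid = if (length(cloud@reflectance))
      cloud@reflValid[keep, , drop = FALSE],
    wavelengths = cloud@wavelengths,
    viewId = if (length(cloud@viewId)) cloud@viewId[keep])
}

## Rigid map of a cloud's coordinates (R %*% p + t).
.transformCloud <- function(cloud, R, t = c(0, 0, 0)) {
  xyz <- sweep(coords(cloud) %*% t(R), 2, t, "+")
  MultispectralPointCloud(xyz, rgb = if (nrow(cloud@rgb)) cloud@rgb,
    reflectance = if (length(cloud@reflectance)) cloud@reflectance,
    reflValid = if (length(cloud@reflectance)) cloud@reflValid,
    wavelengths = cloud@wavelengths,
    viewId = if (length(cloud@viewId)) cloud@viewId)
}

#' Rough registration of a turntable view into the unified frame
#'
#' Translates by minus the axis centre, rotates with \code{Rx(alpha)} then
#' \code{Rz(beta)} (bringing the calibrated axis onto +Y; see
#' [axisAngles()]), then undoes the turntable rotation of this view by
#' applying the printed Y-rotation with angle \code{gamma}. The reference
#' view (gamma = 0) receives only the axis-alignment transform. The composed
#' map is rigid: pairwise distances are preserved.
#'
#' @param cloud a [MultispectralPointCloud-class] in the camera frame.
#' @param calib an [AxisCalibration-class].
#' @param gamma turntable rotation angle of this view relative to the
#'   reference view, degrees in [0, 360).
#' @return the cloud in the unified (axis-aligned, de-rotated) frame.
#' @export
roughRegister <- function(cloud, calib, gamma = 0) {
  stopifnot(is(cloud, "MultispectralPointCloud"), is(calib, "AxisCalibration"))
  if (gamma < 0 || gamma >= 360)
    .mspStop("msp_value_error", "gamma must lie in [0, 360)")
  ang <- axisAngles(axisDirection(calib))
  ## axis alignment first (Rx(alpha) Rz(beta)), then the Y "inverse rotation"
  ## by the view's turntable angle
  A <- .Rx(ang$alpha * pi / 180) %*% .Rz(ang$beta * pi / 180)
  R <- .Ry(gamma * pi / 180) %*% A
  .transformCloud(cloud, R, t = -as.numeric(R %*% axisCenter(calib)))
}

#' Point-to-point ICP refinement
#'
#' Alternates nearest-neighbour matching (k-d tree, correspondences gated at
#' \code{maxCorrDist}) with least-squares rigid alignment (Kabsch) of the
#' matched pairs, until the inlier RMSE improves by less than \code{tol} or
#' \code{maxIter} is reached.
#'
#' @param source,target [MultispectralPointCloud-class] objects or N x 3
#'   matrices (m); the returned transform applies to \code{source}.
#' @param maxIter maximum iterations (default 50).
#' @param tol RMSE improvement threshold for convergence (default 1e-6).
#' @param maxCorrDist correspondence gating distance, m (default 0.01).
#' @return list with \code{R}, \code{t} (the rigid map source -> target),
#'   \code{fitness} (inlier fraction at convergence), \code{rmse} (inlier
#'   RMSE, m) and \code{history} (per-iteration RMSE).
#' @export
icpRefine <- function(source, target, maxIter = 50L, tol = 1e-6,
                      maxCorrDist = 0.01) {
  S <- if (is(source, "MultispectralPointCloud")) coords(source) else as.matrix(source)
  T <- if (is(target, "MultispectralPointCloud")) coords(target) else as.matrix(target)
  if (!nrow(S) || !nrow(T))
    .mspStop("msp_empty_cloud_error", "both clouds must be non-empty")
  R <- diag(3); t <- c(0, 0, 0)
  prev <- Inf; history <- numeric(0); fitness <- 0
  for (it in seq_len(maxIter)) {
    Sc <- sweep(S %*% t(R), 2, t, "+")
    nn <- RANN::nn2(T, Sc, k = 1)
    inl <- which(nn$nn.dists[, 1] <= maxCorrDist)
    if (!length(inl))
      .mspStop("msp_registration_error",
               "no correspondences within maxCorrDist")
    al <- kabschAlign(Sc[inl, , drop = FALSE],
                      T[nn$nn.idx[inl, 1], , drop = FALSE])
    R <- al$R %*% R
    t <- as.numeric(al$R %*% t) + al$t
    Sc <- sweep(S %*% t(R), 2, t, "+")
    nn <- RANN::nn2(T, Sc, k = 1)
    inl <- which(nn$nn.dists[, 1] <= maxCorrDist)
    rmse <- if (length(inl)) sqrt(mean(nn$nn.dists[inl, 1]^2)) else Inf
    fitness <- length(inl) / nrow(S)
    history <- c(history, rmse)
    if (is.finite(prev) && prev - rmse < tol) break
    prev <- rmse
  }
  list(R = R, t = t, fitness = fitness, rmse = rmse, history = history)
}

#' Reconstruct a multispectral 3-D point cloud from turntable views
#'
#' Each view is back-projected ([depthToCloud()]), ROI-filtered, and
#' rough-registered about the calibrated axis ([roughRegister()]); the views
#' are then chained with sequential ICP in acquisition order (view 2 is
#' refined against view 1, view 3 against the merged result, and so on). The
#' first view is the reference view. Spectral attributes ride along
#' unchanged, so the result is a multispectral point cloud with per-point
#' view provenance.
#'
#' @param views list of views, each a list with \code{depth} (matrix, mm),
#'   \code{stack} (aligned channel stack or NULL) and \code{gamma}
#'   (turntable angle, degrees).
#' @param calib an [AxisCalibration-class].
#' @param intr a [cameraIntrinsics()] object.
#' @param roi optional ROI box (see [roiFilter()]).
#' @param icpParams list overriding [icpRefine()] defaults
#'   (\code{maxIter}, \code{tol}, \code{maxCorrDist}).
#' @return A [MultispectralPointCloud-class] in the unified frame.
#' @export
reconstructViews <- function(views, calib, intr, roi = NULL,
                             icpParams = list()) {
  if (length(views) < 2L)
    .mspStop("msp_value_error", "need at least 2 views")
  reg <- lapply(seq_along(views), function(k) {
    v <- views[[k]]
    cl <- depthToCloud(v$depth, intr, attrs = v$stack)
    if (!is.null(roi)) cl <- roiFilter(cl, roi)
    cl <- roughRegister(cl, calib, gamma = v$gamma)
    cl@viewId <- rep(k, nPoints(cl))
    cl
  })
  merged <- reg[[1]]
  for (k in seq_along(reg)[-1]) {
    src <- reg[[k]]
    icp <- do.call(icpRefine, c(list(source = src, target = merged), icpParams))
    src <- .transformCloud(src, icp$R, icp$t)
    merged <- .concatClouds(merged, src)
  }
  merged
}

.concatClouds <- function(a, b) {
  stopifnot(identical(a@wavelengths, b@wavelengths))
  hasRefl <- length(a@reflectance) > 0 || length(b@reflectance) > 0
  bindRefl <- function(x, what) {
    if (length(x@reflectance)) slot(x, what) else
      matrix(if (what == "reflValid") FALSE else NA_real_,
             nPoints(x), length(a@wavelengths))
  }
  MultispectralPointCloud(
    rbind(coords(a), coords(b)),
    rgb = if (nrow(a@rgb) && nrow(b@rgb)) rbind(a@rgb, b@rgb),
    reflectance = if (hasRefl) rbind(bindRefl(a, "reflectance"),
                                     bindRefl(b, "reflectance")),
    reflValid = if (hasRefl) rbind(bindRefl(a, "reflValid"),
                                   bindRefl(b, "reflValid")),
    wavelengths = a@wavelengths,
    viewId = c(if (length(a@viewId)) a@viewId else rep(1L, nPoints(a)),
               if (length(b@viewId)) b@viewId else rep(2L, nPoints(b))))
}
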