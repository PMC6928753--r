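## Turntable rotation-axis self-calibration from two colour-sticker
## observations taken 180 degrees apart. A half-turn maps each sticker centre
## to its antipode across the axis, so the midpoint of each sticker pair lies
## on the axis, and the two chords (Y1-Y2, R1-R2) are both perpendicular to
## the axis direction.

## Default RGB gates (values in [0,1]): yellow = R,G high + B low;
## red = R high + G,B low.
.defaultStickerThresholds <- function() {
  list(
    yellow = list(min = c(0.6, 0.6, 0.0), max = c(1.0, 1.0, 0.35)),
    red    = list(min = c(0.6, 0.0, 0.0), max = c(1.0, 0.35, 0.35)))
}

#' Locate calibration-sticker centroids in a coloured point cloud
#'
#' Points are gated per sticker colour with per-channel min/max bounds in RGB
#' space; each sticker centre is the arithmetic mean of the passing points.
#'
#' @param cloud a [MultispectralPointCloud-class] with per-point RGB.
#' @param thresholds list with elements \code{yellow} and \code{red}, each a
#'   list of numeric(3) \code{min} and \code{max} RGB bounds (defaults target
#'   saturated yellow/red stickers).
#' @return list with \code{yellow}, \code{red} (3-vectors, m) and
#'   \code{nPoints} (named integer(2)).
#' @export
stickerCentroids <- function(cloud, thresholds = .defaultStickerThresholds()) {
  stopifnot(is(cloud, "MultispectralPointCloud"))
  rgb <- pointColors(cloud)
  if (!nrow(rgb))
    .mspStop("msp_calibration_error", "cloud has no per-point RGB")
  xyz <- coords(cloud)
  gate <- function(th) {
    sel <- rgb[, 1] >= th$min[1] & rgb[, 1] <= th$max[1] &
           rgb[, 2] >= th$min[2] & rgb[, 2] <= th$max[2] &
           rgb[, 3] >= th$min[3] & rgb[, 3] <= th$max[3]
    if (sum(sel) < 3L)
      .mspStop("msp_calibration_error",
               sprintf("only %d points passed a sticker colour gate (need >= 3)",
                       sum(sel)))
    list(center = colMeans(xyz[sel, , drop = FALSE]), n = sum(sel))
  }
  y <- gate(thresholds$yellow); r <- gate(thresholds$red)
  list(yellow = y$center, red = r$center,
       nPoints = c(yellow = y$n, red = r$n))
}

#' Estimate the turntable rotation axis from two 180-degree observations
#'
#' The axis centre is the mean of midpoint(Y1, Y2) and midpoint(R1, R2) (a
#' half-turn maps each sticker to its antipode, so both midpoints lie on the
#' axis; they must agree within \code{midpointTol}). The axis direction is
#' the normalised cross product (Y1 - Y2) x (R1 - R2), with its sign chosen
#' so the y-component (camera up) is positive.
#'
#' @param obs0,obs180 sticker observations (as from [stickerCentroids()]) at
#'   turntable angles 0 and 180 degrees.
#' @param midpointTol maximum allowed disagreement of the two midpoints, m
#'   (default 5e-3).
#' @param minChordAngleDeg minimum angle between the two chords, degrees
#'   (default 5): nearly parallel chords leave the axis ill-conditioned.
#' @return An [AxisCalibration-class].
#' @export
estimateAxis <- function(obs0, obs180, midpointTol = 5e-3,
                         minChordAngleDeg = 5) {
  cy <- obs0$yellow - obs180$yellow
  cr <- obs0$red - obs180$red
  ny <- sqrt(sum(cy^2)); nr <- sqrt(sum(cr^2))
  if (ny < 1e-9 || nr < 1e-9)
    .mspStop("msp_axis_error",
             "zero-length sticker chord: did the turntable rotate?")
  cosAng <- abs(sum(cy * cr)) / (ny * nr)
  if (cosAng > cos(minChordAngleDeg * pi / 180))
    .mspStop("msp_axis_error",
             sprintf("sticker chords are nearly parallel (angle < %g deg)",
                     minChordAngleDeg))
  my <- (obs0$yellow + obs180$yellow) / 2
  mr <- (obs0$red + obs180$red) / 2
  if (sqrt(sum((my - mr)^2)) > midpointTol)
    .mspStop("msp_axis_error",
             sprintf("sticker midpoints disagree by %.4f m (tol %.4f m)",
                     sqrt(sum((my - mr)^2)), midpointTol))
  dir <- c(cy[2] * cr[3] - cy[3] * cr[2],
           cy[3] * cr[1] - cy[1] * cr[3],
           cy[1] * cr[2] - cy[2] * cr[1])
  dir <- dir / sqrt(sum(dir^2))
  if (dir[2] < 0) dir <- -dir
  AxisCalibration(center = (my + mr) / 2, direction = dir)
}

#' Axis-alignment rotation angles
#'
#' Returns the rotation angles \code{alpha} (about X) and \code{beta} (about
#' Z) such that applying the rigid-registration rotation matrices in their
#' printed order, \code{Rx(alpha) \%*\% Rz(beta)}, maps \code{axisDir} onto
#' the +Y axis. \code{beta} relates to the axis projection on the XOY plane
#' (\code{atan2(-a, b)}), \code{alpha} to the remaining YOZ-plane tilt
#' (\code{atan2(-c, sqrt(a^2 + b^2))}); for an axis tilted towards +Z,
#' \code{alpha} is negative under this sign convention.
#'
#' @param axisDir unit 3-vector (a, b, c) with positive y-component.
#' @return list with \code{alpha}, \code{beta} in degrees.
#' @export
axisAngles <- function(axisDir) {
  if (abs(sqrt(sum(axisDir^2)) - 1) > 1e-6)
    .mspStop("msp_value_error", "axisDir must be a unit vector")
  a <- axisDir[1]; b <- axisDir[2]; c <- axisDir[3]
  if (abs(b) < 1e-12 && (abs(a) < 1e-12 || abs(c) < 1e-12))
    .mspStop("msp_axis_error",
             "axis orthogonal to Y with a vanishing projection: angles ambiguous")
  beta <- atan2(-a, b)
  alpha <- atan2(-c, sqrt(a^2 + b^2))
  list(alpha = alpha * 180 / pi, beta = beta * 180 / pi)
}

#' Persist / load an axis calibration (JSON)
#'
#' When the depth sensor and turntable do not move between sessions the
#' calibration can be cached and reused.
#'
#' @param calib an [AxisCalibration-class].
#' @param path JSON file path.
#' @param residuals optional named numeric of calibration residuals.
#' @return \code{writeAxisCalibration}: \code{path}, invisibly.
#' @export
writeAxisCalibration <- function(calib, path, residuals = NULL) {
  stopifnot(is(calib, "AxisCalibration"))
  jsonlite::write_json(
    list(axis_center_m = axisCenter(calib), axis_dir = axisDirection(calib),
         residuals = as.list(residuals %||% list())),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeAxisCalibration
#' @return \code{readAxisCalibration}: an [AxisCalibration-class].
#' @export
readAxisCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  AxisCalibration(center = x$axis_center_m, direction = x$axis_dir)
}
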