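#' @import methods
NULL

#' Spectral reflectance cube
#'
#' An \code{H x W x B} stack of per-band reflectance images sharing one pixel
#' grid, with one wavelength (nm) per band and a single 2-D validity mask
#' (one mask suffices because all bands always undergo the same geometric
#' transform).
#'
#' @slot values numeric array, rows x cols x bands; reflectance, >= 0.
#' @slot wavelengths strictly increasing numeric vector (nm), one per band.
#' @slot mask logical matrix, rows x cols; FALSE marks pixels with no valid
#'   source (e.g. mapped from outside the image during resampling).
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(values = "array", wavelengths = "numeric", mask = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a rows x cols x bands array")
    if (length(object@wavelengths) != d[3L])
      return("need one wavelength per band")
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      return("wavelengths must be strictly increasing")
    if (!is.logical(object@mask) || !all(dim(object@mask) == d[1:2]))
      return("mask must be a logical rows x cols matrix")
    v <- object@values[object@mask[rep(seq_len(d[1] * d[2]), d[3])] &
                         !is.na(object@values)]
    if (length(v) && any(v < 0)) return("reflectance must be non-negative")
    TRUE
  })

#' Image-to-image registration transform
#'
#' Similarity transform linking a moving image's pixel frame to a fixed
#' image's pixel frame: scale by \code{sigma} and rotate by \code{theta0}
#' about the image centre, then translate by \code{(x0, y0)} (columns, rows).
#'
#' @slot x0,y0 translation in pixels (columns, rows).
#' @slot theta0 rotation in degrees, in (-180, 180]; positive rotates image
#'   content from +x (columns) towards +y (rows).
#' @slot sigma isotropic scale factor, > 0.
#' @exportClass RegistrationTransform
setClass("RegistrationTransform",
  representation(x0 = "numeric", y0 = "numeric", theta0 = "numeric",
                 sigma = "numeric"),
  validity = function(object) {
    for (s in c("x0", "y0", "theta0", "sigma")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v)) return(paste(s, "must be a finite scalar"))
    }
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@theta0 <= -180 || object@theta0 > 180)
      return("theta0 must lie in (-180, 180]")
    TRUE
  })

#' Turntable rotation-axis calibration
#'
#' @slot center numeric(3), a point on the rotation axis (m, depth-camera frame).
#' @slot direction unit numeric(3), axis direction; by convention the
#'   y-component (camera up) is positive.
#' @exportClass AxisCalibration
setClass("AxisCalibration",
  representation(center = "numeric", direction = "numeric"),
  validity = function(object) {
    if (length(object@center) != 3L || !all(is.finite(object@center)))
      return("center must be a finite 3-vector")
    if (length(object@direction) != 3L || !all(is.finite(object@direction)))
      return("direction must be a finite 3-vector")
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
      return("direction must be a unit vector (|norm - 1| <= 1e-9)")
    TRUE
  })

#' Multispectral 3-D point cloud
#'
#' Point coordinates plus optional per-point colour and per-point, per-band
#' reflectance. Reflectance entries can be individually invalid (a point seen
#' by the depth camera but outside the spectral image); validity is tracked in
#' \code{reflValid}, never encoded as zero reflectance.
#'
#' @slot coords N x 3 numeric matrix, metres.
#' @slot rgb N x 3 matrix in [0, 1], or a 0 x 3 matrix when absent.
#' @slot reflectance N x B matrix, or 0 x 0 when absent.
#' @slot reflValid logical matrix, same shape as \code{reflectance}.
#' @slot wavelengths numeric(B), nm.
#' @slot viewId integer(N), provenance (acquisition view), or length 0.
#' @exportClass MultispectralPointCloud
setClass("MultispectralPointCloud",
  representation(coords = "matrix", rgb = "matrix", reflectance = "matrix",
                 reflValid = "matrix", wavelengths = "numeric",
                 viewId = "integer"),
  validity = function(object) {
    if (ncol(object@coords) != 3L) return("coords must be N x 3")
    if (!all(is.finite(object@coords))) return("coords must be finite")
    n <- nrow(object@coords)
    if (nrow(object@rgb) && (nrow(object@rgb) != n || ncol(object@rgb) != 3L))
      return("rgb must be N x 3 or empty")
    if (length(object@reflectance)) {
      if (nrow(object@reflectance) != n)
        return("reflectance must have one row per point")
      if (!identical(dim(object@reflValid), dim(object@reflectance)))
        return("reflValid must match reflectance shape")
      if (ncol(object@reflectance) != length(object@wavelengths))
        return("need one wavelength per reflectance column")
    }
    if (length(object@viewId) && length(object@viewId) != n)
      return("viewId must have one entry per point")
    TRUE
  })

#' Directed Hausdorff distance statistics
#'
#' The directed nearest-neighbour distance set from a reconstructed cloud to a
#' reference cloud (cm), with its mean, population standard deviation, maximum,
#' and the proportion of distances falling in fixed segments.
#'
#' @slot distances numeric, per-point nearest-neighbour distances (cm), >= 0.
#' @slot hdAvg,hdStd,hdMax summary statistics (cm); \code{hdStd} uses the
#'   population (divide-by-N) convention.
#' @slot segmentProps numeric(5), percentages in the bins
#'   (0, 0.1], (0.1, 0.3], (0.3, 0.6], (0.6, 1.0], (1.0, Inf) cm; zeros count
#'   in the first bin; sums to 100.
#' @exportClass HDStats
setClass("HDStats",
  representation(distances = "numeric", hdAvg = "numeric", hdStd = "numeric",
                 hdMax = "numeric", segmentProps = "numeric"),
  validity = function(object) {
    if (!length(object@distances)) return("distance set must be non-empty")
    if (any(object@distances < 0)) return("distances must be >= 0")
    if (length(object@segmentProps) != 5L)
      return("segmentProps must have 5 bins")
    if (abs(sum(object@segmentProps) - 100) > 0.01)
      return("segmentProps must sum to 100 (within 0.01)")
    TRUE
  })

#' Sample-by-wavelength spectra matrix
#'
#' @slot reflectance samples x wavelengths numeric matrix, no missing values.
#' @slot wavelengths strictly increasing numeric vector (nm).
#' @slot sampleIds character, one per row.
#' @exportClass SpectraMatrix
setClass("SpectraMatrix",
  representation(reflectance = "matrix", wavelengths = "numeric",
                 sampleIds = "character"),
  validity = function(object) {
    if (ncol(object@reflectance) != length(object@wavelengths))
      return("one wavelength per column required")
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      return("wavelengths must be strictly increasing")
    if (anyNA(object@reflectance)) return("reflectance must have no NAs")
    if (length(object@sampleIds) != nrow(object@reflectance))
      return("one sample id per row required")
    TRUE
  })

#' Characteristic-wavelength selection result
#'
#' @slot nutrient one of "N", "P", "K" (or any label).
#' @slot wavelengths selected wavelengths (nm), increasing.
#' @slot provenance character, per wavelength: "RF-peak" (random-frog
#'   probability peak surviving the screens) or "PCA-CC-supplement".
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(nutrient = "character", wavelengths = "numeric",
                 provenance = "character"),
  validity = function(object) {
    if (length(object@wavelengths) != length(object@provenance))
      return("one provenance tag per wavelength required")
    ok <- object@provenance %in% c("RF-peak", "PCA-CC-supplement")
    if (!all(ok)) return("unknown provenance tag")
    TRUE
  })

## ---- constructors ----------------------------------------------------------

#' Create a SpectralCube
#'
#' @param values rows x cols x bands array (a matrix is treated as one band).
#' @param wavelengths numeric, nm, one per band, strictly increasing.
#' @param mask optional logical validity matrix; default all-valid.
#' @return A [SpectralCube-class] object.
#' @export
SpectralCube <- function(values, wavelengths, mask = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  new("SpectralCube", values = values, wavelengths = as.numeric(wavelengths),
      mask = mask)
}

#' Create a RegistrationTransform
#'
#' @param x0,y0 translation in pixels (columns, rows).
#' @param theta0 rotation, degrees, in (-180, 180].
#' @param sigma scale factor, > 0.
#' @return A [RegistrationTransform-class] object.
#' @export
RegistrationTransform <- function(x0 = 0, y0 = 0, theta0 = 0, sigma = 1) {
  new("RegistrationTransform", x0 = as.numeric(x0), y0 = as.numeric(y0),
      theta0 = as.numeric(theta0), sigma = as.numeric(sigma))
}

#' Create an AxisCalibration
#'
#' @param center point on the axis, metres (depth-camera frame).
#' @param direction axis direction; normalised internally.
#' @return An [AxisCalibration-class] object.
#' @export
AxisCalibration <- function(center, direction) {
  direction <- direction / sqrt(sum(direction^2))
  new("AxisCalibration", center = as.numeric(center),
      direction = as.numeric(direction))
}

#' Create a MultispectralPointCloud
#'
#' @param coords N x 3 matrix, metres.
#' @param rgb optional N x 3 colour matrix in [0, 1].
#' @param reflectance optional N x B reflectance matrix.
#' @param reflValid optional logical N x B validity matrix (default: finite
#'   entries of \code{reflectance}).
#' @param wavelengths numeric(B), nm.
#' @param viewId optional integer per-point view provenance.
#' @return A [MultispectralPointCloud-class] object.
#' @export
MultispectralPointCloud <- function(coords, rgb = NULL, reflectance = NULL,
                                    reflValid = NULL, wavelengths = numeric(),
                                    viewId = NULL) {
  coords <- unname(as.matrix(coords))
  if (!is.null(rgb)) rgb <- unname(as.matrix(rgb))
  if (!is.null(reflectance)) reflectance <- unname(as.matrix(reflectance))
  if (!is.null(reflValid)) reflValid <- unname(as.matrix(reflValid))
  if (is.null(rgb)) rgb <- matrix(numeric(), 0L, 3L)
  if (is.null(reflectance)) {
    reflectance <- matrix(numeric(), 0L, 0L)
    reflValid <- matrix(logical(), 0L, 0L)
  } else {
    reflectance <- as.matrix(reflectance)
    if (is.null(reflValid)) reflValid <- is.finite(reflectance)
  }
  if (is.null(viewId)) viewId <- integer()
  new("MultispectralPointCloud", coords = coords, rgb = as.matrix(rgb),
      reflectance = reflectance, reflValid = reflValid,
      wavelengths = as.numeric(wavelengths), viewId = as.integer(viewId))
}

#' Create a SpectraMatrix
#'
#' @param reflectance samples x wavelengths matrix.
#' @param wavelengths numeric, nm.
#' @param sampleIds optional character ids (default "S1".."Sn").
#' @return A [SpectraMatrix-class] object.
#' @export
SpectraMatrix <- function(reflectance, wavelengths, sampleIds = NULL) {
  reflectance <- as.matrix(reflectance)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(reflectance)))
  new("SpectraMatrix", reflectance = reflectance,
      wavelengths = as.numeric(wavelengths), sampleIds = as.character(sampleIds))
}
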