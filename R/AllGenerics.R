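#' Accessors for msplant3d classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `wavelengths()` (nm), `coords()` (N x 3 m), `reflectance()`,
#' `reflectanceValid()`, `pointColors()`, `viewIds()`, `nPoints()`,
#' `cubeValues()`, `cubeMask()`, `nBands()`, `axisCenter()`, `axisDirection()`,
#' `hdDistances()`, `hdSummary()`, `segmentProportions()`.
#'
#' @param x an msplant3d object.
#' @return The slot contents (see each method's class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))
#' @rdname accessors
#' @export
setGeneric("reflectanceValid", function(x) standardGeneric("reflectanceValid"))
#' @rdname accessors
#' @export
setGeneric("pointColors", function(x) standardGeneric("pointColors"))
#' @rdname accessors
#' @export
setGeneric("viewIds", function(x) standardGeneric("viewIds"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))
#' @rdname accessors
#' @export
setGeneric("cubeMask", function(x) standardGeneric("cubeMask"))
#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))
#' @rdname accessors
#' @export
setGeneric("axisCenter", function(x) standardGeneric("axisCenter"))
#' @rdname accessors
#' @export
setGeneric("axisDirection", function(x) standardGeneric("axisDirection"))
#' @rdname accessors
#' @export
setGeneric("hdDistances", function(x) standardGeneric("hdDistances"))
#' @rdname accessors
#' @export
setGeneric("hdSummary", function(x) standardGeneric("hdSummary"))
#' @rdname accessors
#' @export
setGeneric("segmentProportions", function(x) standardGeneric("segmentProportions"))

#' @rdname accessors
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "MultispectralPointCloud", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "SpectraMatrix", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "SelectionResult", function(x) x@wavelengths)
#' @rdname accessors
setMethod("coords", "MultispectralPointCloud", function(x) x@coords)
#' @rdname accessors
setMethod("reflectance", "MultispectralPointCloud", function(x) x@reflectance)
#' @rdname accessors
setMethod("reflectance", "SpectraMatrix", function(x) x@reflectance)
#' @rdname accessors
setMethod("reflectanceValid", "MultispectralPointCloud", function(x) x@reflValid)
#' @rdname accessors
setMethod("pointColors", "MultispectralPointCloud", function(x) x@rgb)
#' @rdname accessors
setMethod("viewIds", "MultispectralPointCloud", function(x) x@viewId)
#' @rdname accessors
setMethod("nPoints", "MultispectralPointCloud", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("cubeValues", "SpectralCube", function(x) x@values)
#' @rdname accessors
setMethod("cubeMask", "SpectralCube", function(x) x@mask)
#' @rdname accessors
setMethod("nBands", "SpectralCube", function(x) dim(x@values)[3L])
#' @rdname accessors
setMethod("axisCenter", "AxisCalibration", function(x) x@center)
#' @rdname accessors
setMethod("axisDirection", "AxisCalibration", function(x) x@direction)
#' @rdname accessors
setMethod("hdDistances", "HDStats", function(x) x@distances)
#' @rdname accessors
setMethod("hdSummary", "HDStats",
          function(x) c(hd_avg = x@hdAvg, hd_std = x@hdStd, hd_max = x@hdMax))
#' @rdname accessors
setMethod("segmentProportions", "HDStats", function(x) x@segmentProps)

## ---- show methods -----------------------------------------------------------

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d x %d px, %d bands (%.1f-%.1f nm), %.1f%% valid\n",
              d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths),
              100 * mean(object@mask)))
})

setMethod("show", "RegistrationTransform", function(object) {
  cat(sprintf(
    "RegistrationTransform: shift (%.3f, %.3f) px, rotation %.3f deg, scale %.4f\n",
    object@x0, object@y0, object@theta0, object@sigma))
})

setMethod("show", "AxisCalibration", function(object) {
  cat(sprintf("AxisCalibration: center (%.4f, %.4f, %.4f) m, direction (%.4f, %.4f, %.4f)\n",
              object@center[1], object@center[2], object@center[3],
              object@direction[1], object@direction[2], object@direction[3]))
})

setMethod("show", "MultispectralPointCloud", function(object) {
  cat(sprintf("MultispectralPointCloud: %d points", nrow(object@coords)))
  if (nrow(object@rgb)) cat(", RGB")
  if (length(object@reflectance))
    cat(sprintf(", %d bands (%.1f%% valid reflectance)",
                ncol(object@reflectance), 100 * mean(object@reflValid)))
  if (length(object@viewId))
    cat(sprintf(", %d views", length(unique(object@viewId))))
  cat("\n")
})

setMethod("show", "HDStats", function(object) {
  cat(sprintf("HDStats: n=%d, HD_avg=%.3f cm, HD_std=%.3f cm, HD_max=%.3f cm\n",
              length(object@distances), object@hdAvg, object@hdStd, object@hdMax))
  cat(sprintf("  segments (0,0.1] (0.1,0.3] (0.3,0.6] (0.6,1] (1,Inf): %s %%\n",
              paste(sprintf("%.2f", object@segmentProps), collapse = " ")))
})

setMethod("show", "SpectraMatrix", function(object) {
  cat(sprintf("SpectraMatrix: %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(object@reflectance), ncol(object@reflectance),
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "SelectionResult", function(object) {
  star <- ifelse(object@provenance == "PCA-CC-supplement", "*", "")
  cat(sprintf("SelectionResult [%s]: %s nm\n", object@nutrient,
              paste0(sprintf("%.1f", object@wavelengths), star, collapse = ", ")))
})
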