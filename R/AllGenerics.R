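#' Pixel matrix of an ImageGrid
#' @param x an `ImageGrid`.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Rotation-center coordinate
#' @param x an `ImageGrid`.
#' @return numeric(1), 0-based pixel coordinate of the rotation center.
#' @export
setGeneric("gridCenter", function(x) standardGeneric("gridCenter"))

#' Projection data matrix of a Sinogram (angles x detector bins)
#' @param x a `Sinogram`.
#' @return numeric matrix.
#' @export
setGeneric("sinoData", function(x) standardGeneric("sinoData"))

#' Projection angles in degrees
#' @param x a `Sinogram`.
#' @return numeric vector.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' Detector-bin offset axis
#' @param x a `Sinogram`.
#' @return numeric vector, unit-spaced, symmetric about 0.
#' @export
setGeneric("tAxis", function(x) standardGeneric("tAxis"))

#' Filter / kernel taps
#' @param x a `RampKernel` or `CorrectionFilter`.
#' @return numeric vector of taps.
#' @export
setGeneric("filterTaps", function(x) standardGeneric("filterTaps"))

#' @rdname pixels
#' @export
setMethod("pixels", "ImageGrid", function(x) x@pixels)

#' @rdname gridCenter
#' @export
setMethod("gridCenter", "ImageGrid", function(x) x@center)

#' @rdname sinoData
#' @export
setMethod("sinoData", "Sinogram", function(x) x@data)

#' @rdname angles
#' @export
setMethod("angles", "Sinogram", function(x) x@angles)

#' @rdname tAxis
#' @export
setMethod("tAxis", "Sinogram", function(x) x@tAxis)

#' @rdname filterTaps
#' @export
setMethod("filterTaps", "RampKernel", function(x) x@taps)

#' @rdname filterTaps
#' @export
setMethod("filterTaps", "CorrectionFilter", function(x) x@taps)

setMethod("show", "ImageGrid", function(object) {
  p <- object@pixels
  cat(sprintf("ImageGrid %d x %d, center %.1f, range [%.4g, %.4g]\n",
              nrow(p), ncol(p), object@center, min(p), max(p)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d detector bins\n",
              nrow(object@data), ncol(object@data)))
  a <- object@angles
  cat(sprintf("  angles %.4g..%.4g deg, t in [%g, %g]\n",
              min(a), max(a), min(object@tAxis), max(object@tAxis)))
})

setMethod("show", "RampKernel", function(object) {
  cat(sprintf("RampKernel h_%d (%s):\n", object@halfWidth,
              if (is.na(object@N)) "asymptotic" else paste0("N = ", object@N)))
  print(round(object@taps, 4))
})

setMethod("show", "CorrectionFilter", function(object) {
  cat(sprintf(
    "CorrectionFilter, %d taps (sum %.4f), design residual %.3g:\n",
    length(object@taps), sum(object@taps), object@residualNorm))
  print(round(object@taps, 4))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: MSE %.4e  UQI %.4f  MI %.4f bits (%d bins)\n",
              object@mse, object@uqi, object@mi, object@nBins))
  if (length(object@sValues))
    cat("  s:", paste(sprintf("%.4f", object@sValues), collapse = ", "), "\n")
})

setMethod("show", "ReconConfig", function(object) {
  cat(sprintf(
    "ReconConfig: size %d, N %s, n %d, maxIter %d, tol %g, %s interpolation\n",
    object@imageSize,
    if (is.na(object@fftLength)) "auto" else object@fftLength,
    object@filterHalfWidth, object@maxIterations, object@stopTolerance,
    object@interpolation))
})

setMethod("show", "RawScan", function(object) {
  cat(sprintf("RawScan: %d x %d frames (projection/background/dark)\n",
              nrow(object@projection), ncol(object@projection)))
})
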