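#' @import methods
NULL

#' Square image on a pixel grid with a rotation-center convention
#'
#' An `ImageGrid` holds a square 2-D intensity map (dimensionless linear
#' attenuation, row 1 at the top) together with the continuous coordinate of
#' the rotation center in 0-based pixel units.  The same coordinate is used
#' along both axes; the default, \eqn{(n-1)/2}, is the geometric center of
#' the grid, so that symmetric objects project symmetrically.
#'
#' @slot pixels numeric matrix, square, all values finite.
#' @slot center numeric(1), rotation-center coordinate in 0-based pixel units.
#' @export
setClass("ImageGrid",
  representation(pixels = "matrix", center = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (nrow(p) != ncol(p)) return("pixels must be square (rows == cols)")
    if (!all(is.finite(p))) return("pixels must all be finite")
    if (length(object@center) != 1L || !is.finite(object@center))
      return("center must be a single finite number")
    TRUE
  })

#' Parallel-beam sinogram
#'
#' Stack of 1-D projections \eqn{p_i(t)}: one row per scanning angle, one
#' column per detector bin.  The detector axis `tAxis` has unit spacing and
#' is symmetric about zero (odd bin count), in pixel units relative to the
#' rotation center.  Angles are in degrees in \eqn{[0, 180)}.
#'
#' @slot data numeric matrix, angles x detector bins, finite.
#' @slot angles numeric vector of projection angles in degrees,
#'   strictly increasing in `[0, 180)`.
#' @slot tAxis numeric vector of detector-bin offsets, unit-spaced and
#'   symmetric about 0.
#' @export
setClass("Sinogram",
  representation(data = "matrix", angles = "numeric", tAxis = "numeric"),
  validity = function(object) {
    if (nrow(object@data) != length(object@angles))
      return("rows(data) must equal length(angles)")
    if (ncol(object@data) != length(object@tAxis))
      return("cols(data) must equal length(tAxis)")
    if (!all(is.finite(object@data))) return("data must be finite")
    if (length(object@angles) < 1L) return("at least one angle is required")
    if (any(diff(object@angles) <= 0))
      return("angles must be strictly increasing")
    if (any(object@angles < 0 | object@angles >= 180))
      return("angles must lie in [0, 180) degrees")
    tt <- object@tAxis
    if (max(abs(tt + rev(tt))) > 1e-9 || max(abs(diff(tt) - 1)) > 1e-9)
      return("tAxis must be unit-spaced and symmetric about 0")
    TRUE
  })

#' Spatial ramp-filter kernel
#'
#' The symmetric \eqn{2n+1}-tap spatial form of the discrete ramp filter:
#' taps are the kernel values \eqn{\beta_N} at integer offsets
#' \eqn{-n, \dots, n} for a DFT length `N` (the asymptotic
#' \eqn{N \to \infty} values when `N` is `NA`).  The center tap is 1/4 and
#' taps at even non-zero offsets vanish (exactly in the asymptotic form,
#' to better than \eqn{10^{-3}} for \eqn{N \ge 64}).
#'
#' @slot taps numeric vector of length `2*halfWidth + 1`, symmetric.
#' @slot halfWidth integer(1).
#' @slot N integer(1), DFT length used, or `NA` for the asymptotic kernel.
#' @export
setClass("RampKernel",
  representation(taps = "numeric", halfWidth = "integer", N = "integer"),
  validity = function(object) {
    m <- length(object@taps)
    if (m != 2L * object@halfWidth + 1L)
      return("taps must have length 2*halfWidth + 1")
    if (!all(is.finite(object@taps))) return("taps must be finite")
    if (max(abs(object@taps - rev(object@taps))) > 1e-12)
      return("taps must be symmetric")
    TRUE
  })

#' Symmetric deconvolution filter for the reprojection residual
#'
#' The \eqn{2n+1}-tap symmetric filter F minimising
#' \eqn{\|h_n \otimes F - \delta\|_2^2} against a ramp kernel
#' \eqn{h_n}, rescaled by `normConstant` so that the taps sum to 2 (the
#' normalisation under which the filter is reported).  `residualNorm` is the
#' deconvolution residual \eqn{\|h_n \otimes F - \delta\|_2} of the
#' unnormalised least-squares solution.
#'
#' @slot taps numeric, symmetric, same length as the kernel it inverts.
#' @slot halfWidth integer(1).
#' @slot N integer(1), DFT length of the kernel inverted (`NA` if asymptotic).
#' @slot normConstant numeric(1), scale applied to the least-squares solution.
#' @slot residualNorm numeric(1).
#' @export
setClass("CorrectionFilter",
  representation(taps = "numeric", halfWidth = "integer", N = "integer",
                 normConstant = "numeric", residualNorm = "numeric"),
  validity = function(object) {
    m <- length(object@taps)
    if (m != 2L * object@halfWidth + 1L)
      return("taps must have length 2*halfWidth + 1")
    if (!all(is.finite(object@taps))) return("taps must be finite")
    if (max(abs(object@taps - rev(object@taps))) > 1e-10)
      return("taps must be symmetric")
    TRUE
  })

#' Reconstruction configuration
#'
#' @slot imageSize integer(1), output image side length.
#' @slot fftLength integer(1), DFT length for ramp filtering; `NA` selects
#'   `max(64, next power of two >= 2 * detector length)`.
#' @slot filterHalfWidth integer(1), half-width n of the ramp kernel the
#'   correction filter is designed against (default 5).
#' @slot maxIterations integer(1), correction iterations (0 = classic FBP).
#' @slot stopTolerance numeric(1), relative improvement in the reprojection
#'   mean-squared residual below which iteration stops.
#' @slot interpolation character(1), `"linear"` or `"nearest"`
#'   back-projection interpolation.
#' @slot seed integer(1), seed for any stochastic fixture (`NA` = none).
#' @export
setClass("ReconConfig",
  representation(imageSize = "integer", fftLength = "integer",
                 filterHalfWidth = "integer", maxIterations = "integer",
                 stopTolerance = "numeric", interpolation = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@imageSize < 1L) return("imageSize must be positive")
    if (object@maxIterations < 0L) return("maxIterations must be >= 0")
    if (object@stopTolerance < 0) return("stopTolerance must be >= 0")
    if (!object@interpolation %in% c("linear", "nearest"))
      return("interpolation must be 'linear' or 'nearest'")
    if (!is.na(object@fftLength) && object@fftLength %% 2L != 0L)
      return("fftLength must be even")
    TRUE
  })

#' Image-quality report
#'
#' Bundle of quality criteria for a (reconstruction, reference) pair:
#' pixelwise mean squared error, global universal quality index, mutual
#' information from an equal-width joint histogram, and optionally the
#' per-stage reprojection residual statistics of an iterative
#' reconstruction.
#'
#' @slot mse numeric(1), >= 0.
#' @slot uqi numeric(1) in `[-1, 1]`.
#' @slot mi numeric(1), >= 0 (bits).
#' @slot sValues numeric vector of per-stage reprojection mean-squared
#'   residuals (may be empty).
#' @slot nBins integer(1), histogram bin count used for `mi`.
#' @export
setClass("QualityReport",
  representation(mse = "numeric", uqi = "numeric", mi = "numeric",
                 sValues = "numeric", nBins = "integer"))

#' Raw scan triplet for flat-/dark-field normalisation
#'
#' Projection, background (flat-field) and dark-field detector frames of
#' identical shape, as non-negative count arrays.
#'
#' @slot projection numeric matrix of detector counts with the sample in
#'   the beam.
#' @slot background numeric matrix, beam on, sample absent.
#' @slot dark numeric matrix, beam off.
#' @export
setClass("RawScan",
  representation(projection = "matrix", background = "matrix",
                 dark = "matrix"),
  validity = function(object) {
    d <- dim(object@projection)
    if (!identical(d, dim(object@background)) ||
        !identical(d, dim(object@dark)))
      return("projection, background and dark must have identical shape")
    if (min(object@projection, object@background, object@dark) < 0)
      return("counts must be non-negative")
    TRUE
  })
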