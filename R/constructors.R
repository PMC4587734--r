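#' Create an ImageGrid
#'
#' @param pixels square numeric matrix.
#' @param center rotation-center coordinate in 0-based pixel units;
#'   defaults to the geometric center `(n - 1) / 2`.
#' @return an [ImageGrid-class] object.
#' @export
ImageGrid <- function(pixels, center = (nrow(pixels) - 1) / 2) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("ImageGrid", pixels = pixels, center = as.numeric(center))
}

#' Create a Sinogram
#'
#' @param data numeric matrix, one row per angle, one column per detector
#'   bin (odd count).
#' @param angles projection angles in degrees, strictly increasing in
#'   `[0, 180)`.
#' @param tAxis detector-bin offsets; defaults to the symmetric unit-spaced
#'   axis implied by `ncol(data)`.
#' @return a [Sinogram-class] object.
#' @export
Sinogram <- function(data, angles,
                     tAxis = seq(-(ncol(data) - 1) / 2,
                                 (ncol(data) - 1) / 2)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("Sinogram", data = data, angles = as.numeric(angles),
      tAxis = as.numeric(tAxis))
}

#' Create a reconstruction configuration
#'
#' @param imageSize side length of the reconstructed image.
#' @param fftLength DFT length for ramp filtering, an even integer, or `NA`
#'   to use `max(64, next power of two >= 2 * detector length)`.
#' @param filterHalfWidth half-width n of the ramp kernel used to design
#'   the correction filter.
#' @param maxIterations number of correction iterations; 0 gives classic FBP.
#' @param stopTolerance relative improvement in the reprojection residual
#'   below which iteration stops early.
#' @param interpolation back-projection interpolation, `"linear"`
#'   (default) or `"nearest"`.
#' @param seed optional integer seed for stochastic fixtures.
#' @return a [ReconConfig-class] object.
#' @export
reconConfig <- function(imageSize, fftLength = NA, filterHalfWidth = 5L,
                        maxIterations = 3L, stopTolerance = 1e-3,
                        interpolation = c("linear", "nearest"),
                        seed = NA) {
  interpolation <- match.arg(interpolation)
  new("ReconConfig",
      imageSize = as.integer(imageSize),
      fftLength = as.integer(fftLength),
      filterHalfWidth = as.integer(filterHalfWidth),
      maxIterations = as.integer(maxIterations),
      stopTolerance = as.numeric(stopTolerance),
      interpolation = interpolation,
      seed = as.integer(seed))
}

#' Create a RawScan
#'
#' @param projection detector counts with the sample in the beam.
#' @param background flat-field counts (beam on, sample absent).
#' @param dark dark-field counts (beam off).
#' @return a [RawScan-class] object.
#' @export
RawScan <- function(projection, background, dark) {
  asm <- function(x) { x <- as.matrix(x); storage.mode(x) <- "double"; x }
  new("RawScan", projection = asm(projection), background = asm(background),
      dark = asm(dark))
}
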