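#' Detector length for a given image size
#'
#' Returns an odd number of detector bins large enough that every pixel of
#' a rotated `imgSize x imgSize` image projects strictly inside the
#' detector at any angle: at least `ceiling(sqrt(2) * imgSize) + 2`.
#'
#' @param imgSize image side length, integer >= 1.
#' @return odd integer bin count.
#' @export
detectorLength <- function(imgSize) {
  stopifnot(length(imgSize) == 1L, imgSize >= 1, imgSize == round(imgSize))
  2L * (as.integer(ceiling(sqrt(2) * imgSize / 2)) + 2L) + 1L
}

#' Forward projection (discrete Radon transform)
#'
#' Pixel-driven parallel-beam projector: every pixel is split into 2x2
#' equal sub-pixels, and each sub-pixel's value/4 is divided linearly
#' between the two detector bins bracketing its projected coordinate
#' \eqn{t = x\cos\theta + y\sin\theta} (coordinates in pixel units
#' relative to the rotation center, y pointing up).  Mass is conserved
#' per angle: each row of the sinogram sums to the image sum.
#'
#' @param img an [ImageGrid-class].
#' @param angles projection angles in degrees, strictly increasing in
#'   `[0, 180)`.
#' @param nbins detector bin count (odd); defaults to
#'   [detectorLength()] of the image size.
#' @return a [Sinogram-class].
#' @examples
#' ph <- headPhantom(32)
#' sg <- forwardProject(ph, seq(0, 179, by = 1))
#' all.equal(rowSums(sinoData(sg)), rep(sum(pixels(ph)), 180))
#' @export
forwardProject <- function(img, angles, nbins = detectorLength(nrow(pixels(img)))) {
  stopifnot(is(img, "ImageGrid"))
  if (length(angles) < 1L) stop("angle list must not be empty")
  data <- cpp_forward_project(img@pixels, angles * pi / 180,
                              as.integer(nbins), img@center)
  Sinogram(data, angles)
}

#' Exact adjoint of the forward projector
#'
#' Applies the transpose of the linear operator implemented by
#' [forwardProject()] (same 2x2 sub-pixel splitting and linear bin
#' weights), mapping a sinogram back to image space.  This is the
#' unfiltered, unscaled backprojection used by the algebraic
#' reconstructors, which require a matched operator pair; it is not the
#' interpolating FBP backprojector.
#'
#' @param sino a [Sinogram-class].
#' @param imageSize output image side length.
#' @param center rotation-center coordinate; defaults to the geometric
#'   center.
#' @return an [ImageGrid-class].
#' @export
projectAdjoint <- function(sino, imageSize,
                           center = (imageSize - 1) / 2) {
  stopifnot(is(sino, "Sinogram"))
  img <- cpp_project_adjoint(sino@data, sino@angles * pi / 180,
                             as.integer(imageSize), center)
  ImageGrid(img, center)
}
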