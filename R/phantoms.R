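#' Ellipse table of the modified Shepp-Logan head phantom
#'
#' The standard 10-ellipse parameterisation in the contrast-enhanced
#' ("modified") intensity variant, on the unit square `[-1, 1]^2`.
#' Columns: additive intensity `A`, semi-axes `a` (x) and `b` (y),
#' center `x0`, `y0`, rotation `phi` in degrees (counter-clockwise).
#'
#' @return a data.frame with 10 rows.
#' @export
sheppLoganEllipses <- function() {
  data.frame(
    A   = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.8740, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0))
}

#' Analytic phantom intensity at continuous coordinates
#'
#' Sum of the intensities of all ellipses containing the point, on the
#' `[-1, 1]^2` phantom coordinate system (y axis pointing up).
#'
#' @param x,y numeric vectors of equal length.
#' @param ellipses ellipse table, by default [sheppLoganEllipses()].
#' @return numeric vector of intensities.
#' @export
phantomIntensity <- function(x, y, ellipses = sheppLoganEllipses()) {
  val <- numeric(length(x))
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    p <- e$phi * pi / 180
    xr <- (x - e$x0) * cos(p) + (y - e$y0) * sin(p)
    yr <- -(x - e$x0) * sin(p) + (y - e$y0) * cos(p)
    val <- val + e$A * ((xr / e$a)^2 + (yr / e$b)^2 <= 1)
  }
  val
}

#' Modified Shepp-Logan head phantom
#'
#' Rasterises the standard 10-ellipse head phantom on a `size x size`
#' grid: each pixel takes the analytic ellipse-sum intensity at its
#' center (no anti-aliasing).  The grid spans `[-1, 1]` along both axes
#' with pixel centers at `((0:(size-1)) - (size-1)/2) / ((size-1)/2)`,
#' matching the common generator convention.  Deterministic.
#'
#' @param size image side length in pixels, integer `>= 16`.
#' @return an [ImageGrid-class] with values in `[0, 1]`; all non-zero
#'   pixels lie inside the inscribed circle.
#' @examples
#' ph <- headPhantom(64)
#' range(pixels(ph))
#' @export
headPhantom <- function(size) {
  if (length(size) != 1L || !is.finite(size) || size != round(size))
    stop("size must be a single integer")
  if (size < 16) stop("size must be >= 16")
  size <- as.integer(size)
  g <- ((0:(size - 1)) - (size - 1) / 2) / ((size - 1) / 2)
  x <- rep(g, each = size)          # column-major: column index varies slowly
  y <- rep(rev(g), times = size)    # row 1 is the top of the image
  img <- matrix(phantomIntensity(x, y), nrow = size, ncol = size)
  # overlapping ellipse intensities cancel exactly (e.g. 1 - 0.8 - 0.2);
  # zap the floating-point dust so the background is exactly zero
  img[abs(img) < 1e-12] <- 0
  ImageGrid(img)
}

#' Add white Gaussian noise to a sinogram
#'
#' Implements the projection noise model \eqn{p = p_0 + \sigma Z} with
#' \eqn{\sigma} = `sigmaFraction * max(p0)` and `Z` i.i.d. standard
#' Gaussian of the same shape.  Reproducible for a fixed seed; the global
#' RNG state is restored on exit.
#'
#' @param sino a [Sinogram-class].
#' @param sigmaFraction noise magnitude as a fraction of `max(p0)`,
#'   non-negative.
#' @param seed integer seed.
#' @return a noisy [Sinogram-class] of the same geometry.
#' @export
addProjectionNoise <- function(sino, sigmaFraction, seed) {
  stopifnot(is(sino, "Sinogram"))
  if (length(sigmaFraction) != 1L || !is.finite(sigmaFraction) ||
      sigmaFraction < 0)
    stop("sigmaFraction must be a single non-negative number")
  if (sigmaFraction == 0) return(sino)
  p0 <- sino@data
  sigma <- sigmaFraction * max(p0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(length(p0)), nrow = nrow(p0))
  Sinogram(p0 + sigma * z, sino@angles, sino@tAxis)
}
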