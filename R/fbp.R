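#' Spatial ramp-kernel value at an integer offset (finite DFT length)
#'
#' Evaluates the spatial-domain coefficient of the discrete ramp filter,
#' \deqn{\beta_N(t) = \frac{1}{N}\sum_{k=-N/2+1}^{N/2} \left|\frac{k}{N}\right|
#'   e^{-i 2\pi k t / N},}
#' i.e. the inverse DFT of the frequency ramp `|k/N|`.  The imaginary part
#' cancels by symmetry; the real value is returned.  `betaN(0, N)` is
#' exactly 1/4 and values at even non-zero offsets are below \eqn{10^{-3}}
#' in magnitude for `N >= 64`.
#'
#' @param t integer offset(s), `|t| < N`.
#' @param N even DFT length, `N >= 4`.
#' @return numeric vector of kernel values.
#' @examples
#' betaN(1, 512)   # ~ -0.1013
#' betaN(3, 64)    # ~ -0.0113
#' @export
betaN <- function(t, N) {
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N %% 2 != 0)
    stop("N must be a single even integer")
  if (N < 4) stop("N must be >= 4")
  if (any(abs(t) >= N)) stop("|t| must be < N")
  k <- c(0:(N / 2), (-N / 2 + 1):(-1))
  w <- abs(k / N)
  vapply(t, function(tt) Re(sum(w * exp(-2i * pi * k * tt / N))) / N,
         numeric(1))
}

#' Asymptotic spatial ramp-kernel value
#'
#' Closed-form limit of [betaN()] as the DFT length grows,
#' \eqn{2\int_0^{1/2} x \cos(2 t \pi x)\,dx}: 1/4 at `t = 0`, zero at even
#' non-zero offsets, and \eqn{-1/(t^2\pi^2)} at odd offsets.
#'
#' @param t integer offset(s).
#' @return numeric vector.
#' @export
betaLimit <- function(t) {
  stopifnot(all(t == round(t)))
  out <- numeric(length(t))
  out[t == 0] <- 0.25
  odd <- t %% 2 != 0
  out[odd] <- -1 / (t[odd]^2 * pi^2)
  out
}

#' Build the symmetric spatial ramp kernel h_n
#'
#' Taps are \eqn{\beta_N} evaluated at offsets `-n ... n` (center exactly
#' 1/4; even offsets essentially zero), or the asymptotic [betaLimit()]
#' values when `N` is `NA`.
#'
#' @param halfWidth half-width n, integer >= 1.
#' @param N even DFT length with `N >= 4 * halfWidth` (so the kernel
#'   support does not wrap), or `NA` for the asymptotic kernel.
#' @return a [RampKernel-class].
#' @examples
#' filterTaps(rampKernel(5, 128))   # the 11-tap kernel, center 0.25
#' @export
rampKernel <- function(halfWidth, N = NA) {
  stopifnot(length(halfWidth) == 1L, halfWidth >= 1,
            halfWidth == round(halfWidth))
  off <- -halfWidth:halfWidth
  if (is.na(N)) {
    taps <- betaLimit(off)
  } else {
    if (N < 4 * halfWidth)
      stop("N must be >= 4 * halfWidth (kernel would wrap)")
    taps <- betaN(off, N)
  }
  taps <- (taps + rev(taps)) / 2       # enforce exact symmetry
  new("RampKernel", taps = taps, halfWidth = as.integer(halfWidth),
      N = as.integer(N))
}

#' Default DFT length for ramp filtering
#'
#' `max(64, smallest power of two >= 2 * L)`; the factor two of padding
#' keeps the circular convolution of the ramp's long `1/t^2` tails from
#' wrapping into the projection support.
#'
#' @param L projection row length.
#' @return even integer DFT length.
#' @export
defaultFFTLength <- function(L) {
  max(64L, 2L^as.integer(ceiling(log2(2 * L))))
}

#' Ramp-filter one projection row
#'
#' Zero-pads the row to length `N`, multiplies DFT bin k by the frequency
#' ramp `|k/N|` for `k` in `[-N/2 + 1, N/2]`, inverse-transforms and
#' truncates to the original length.  With `N == length(p)` (no padding)
#' this equals the circular convolution of the row with the `betaN`
#' kernel.
#'
#' @param p numeric projection row.
#' @param N even DFT length `>= length(p)`; default [defaultFFTLength()].
#' @return filtered numeric row, same length as `p`.
#' @export
rampFilterRow <- function(p, N = defaultFFTLength(length(p))) {
  L <- length(p)
  if (N %% 2 != 0) stop("N must be even")
  if (N < L) stop("N must be >= length(p)")
  w <- pmin(0:(N - 1), N - (0:(N - 1))) / N
  q <- stats::fft(stats::fft(c(p, numeric(N - L))) * w, inverse = TRUE) / N
  if (max(abs(Im(q))) > 1e-9 * (sqrt(mean(Re(q)^2)) + 1e-300))
    warning("non-negligible imaginary residue after inverse DFT")
  Re(q)[seq_len(L)]
}

#' Ramp-filter every row of a sinogram
#'
#' @param sino a [Sinogram-class].
#' @param N even DFT length; default [defaultFFTLength()] of the row
#'   length.
#' @return a [Sinogram-class] of filtered rows.
#' @export
rampFilterSinogram <- function(sino, N = defaultFFTLength(ncol(sinoData(sino)))) {
  P <- sino@data
  L <- ncol(P)
  if (N %% 2 != 0) stop("N must be even")
  if (N < L) stop("N must be >= row length")
  w <- pmin(0:(N - 1), N - (0:(N - 1))) / N
  pad <- matrix(0, nrow(P), N)
  pad[, seq_len(L)] <- P
  Q <- Re(t(stats::mvfft(stats::mvfft(t(pad)) * w, inverse = TRUE))) / N
  Sinogram(Q[, seq_len(L), drop = FALSE], sino@angles, sino@tAxis)
}

#' Back-project filtered projections
#'
#' For each pixel and each angle, accumulates the interpolated value of
#' the filtered row at \eqn{t = x\cos\theta + y\sin\theta} (pixel
#' coordinates relative to the rotation center), then scales by
#' \eqn{\pi / K} where K is the number of angles.  Samples falling
#' outside the detector axis contribute zero.
#'
#' @param filtered a [Sinogram-class] of ramp-filtered rows.
#' @param imageSize output image side length.
#' @param interpolation `"linear"` (default) or `"nearest"` sampling of
#'   the filtered rows.
#' @param center rotation-center coordinate; default geometric center.
#' @return an [ImageGrid-class].
#' @export
backproject <- function(filtered, imageSize,
                        interpolation = c("linear", "nearest"),
                        center = (imageSize - 1) / 2) {
  stopifnot(is(filtered, "Sinogram"))
  interpolation <- match.arg(interpolation)
  img <- cpp_backproject(filtered@data, filtered@angles * pi / 180,
                         as.integer(imageSize), center,
                         interpolation == "linear")
  ImageGrid(img, center)
}

#' Classic filtered back-projection reconstruction
#'
#' Ramp-filters every projection row ([rampFilterSinogram()]) and
#' back-projects with the configured interpolation ([backproject()]).
#' Deterministic and linear in the sinogram.
#'
#' @param sino a [Sinogram-class].
#' @param cfg a [ReconConfig-class]; `cfg@imageSize` sets the output
#'   size, `cfg@fftLength` the DFT length (`NA` = automatic).
#' @return an [ImageGrid-class].
#' @examples
#' ph <- headPhantom(32)
#' sg <- forwardProject(ph, seq(0, 178, by = 2))
#' rec <- fbpReconstruct(sg, reconConfig(32))
#' @export
fbpReconstruct <- function(sino, cfg = reconConfig(guessImageSize(sino))) {
  stopifnot(is(sino, "Sinogram"), is(cfg, "ReconConfig"))
  N <- if (is.na(cfg@fftLength)) defaultFFTLength(ncol(sino@data)) else cfg@fftLength
  backproject(rampFilterSinogram(sino, N), cfg@imageSize, cfg@interpolation)
}

#' Largest image size whose projections fit a sinogram's detector
#'
#' Inverts the [detectorLength()] formula; convenience for reconstructing
#' at the acquisition size.
#'
#' @param sino a [Sinogram-class].
#' @return integer image side length.
#' @export
guessImageSize <- function(sino) {
  L <- ncol(sinoData(sino))
  size <- floor((L - 5L) / sqrt(2))
  while (detectorLength(size + 1L) <= L) size <- size + 1L
  as.integer(size)
}
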