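# Algebraic / statistical reference reconstructors over the same
# projector pair (forward operator A = forwardProject, exact adjoint
# A^T = projectAdjoint).  These exist for accuracy and robustness
# comparisons with the correction loop, not for speed.

safeDiv <- function(num, den, eps = 1e-12) {
  out <- num / pmax(den, eps)
  out[den <= eps] <- 0
  out
}

checkInit <- function(sino, init) {
  stopifnot(is(sino, "Sinogram"), is(init, "ImageGrid"))
}

#' SIRT reconstruction
#'
#' Simultaneous Iterative Reconstruction Technique with row/column-sum
#' normalisation:
#' \deqn{f \leftarrow f + \lambda\, C^{-1} A^T R^{-1} (p - A f)}
#' with `R = diag(A 1)` (per-ray weight) and `C = diag(A^T 1)` (per-pixel
#' weight).  `iterations = 0` returns the initial image unchanged.
#'
#' @param sino measured [Sinogram-class].
#' @param init initial [ImageGrid-class] (e.g. an FBP reconstruction or
#'   zeros).
#' @param iterations number of sweeps, >= 0.
#' @param relax relaxation factor lambda (default 1).
#' @return an [ImageGrid-class].
#' @export
sirt <- function(sino, init, iterations, relax = 1.0) {
  checkInit(sino, init)
  n <- nrow(init@pixels)
  L <- ncol(sino@data)
  ones <- ImageGrid(matrix(1, n, n), init@center)
  rowW <- forwardProject(ones, sino@angles, nbins = L)@data
  colW <- projectAdjoint(Sinogram(matrix(1, nrow(sino@data), L),
                                  sino@angles, sino@tAxis),
                         n, init@center)@pixels
  f <- init@pixels
  for (it in seq_len(iterations)) {
    r <- sino@data - forwardProject(ImageGrid(f, init@center),
                                    sino@angles, nbins = L)@data
    bp <- projectAdjoint(Sinogram(safeDiv(r, rowW), sino@angles, sino@tAxis),
                         n, init@center)@pixels
    f <- f + relax * safeDiv(bp, colW)
  }
  ImageGrid(f, init@center)
}

#' SART reconstruction
#'
#' Angle-sequential algebraic reconstruction: one additive update per
#' projection angle per sweep, using the single-angle forward operator
#' and its adjoint with the same normalisations as [sirt()].
#'
#' @inheritParams sirt
#' @return an [ImageGrid-class].
#' @export
sart <- function(sino, init, iterations, relax = 1.0) {
  checkInit(sino, init)
  n <- nrow(init@pixels)
  L <- ncol(sino@data)
  ones <- ImageGrid(matrix(1, n, n), init@center)
  f <- init@pixels
  K <- length(sino@angles)
  rowW <- vector("list", K); colW <- vector("list", K)
  for (k in seq_len(K)) {
    ak <- sino@angles[k]
    rowW[[k]] <- forwardProject(ones, ak, nbins = L)@data
    colW[[k]] <- projectAdjoint(Sinogram(matrix(1, 1, L), ak, sino@tAxis),
                                n, init@center)@pixels
  }
  for (it in seq_len(iterations)) {
    for (k in seq_len(K)) {
      ak <- sino@angles[k]
      pk <- sino@data[k, , drop = FALSE]
      r <- pk - forwardProject(ImageGrid(f, init@center), ak, nbins = L)@data
      bp <- projectAdjoint(Sinogram(safeDiv(r, rowW[[k]]), ak, sino@tAxis),
                           n, init@center)@pixels
      f <- f + relax * safeDiv(bp, colW[[k]])
    }
  }
  ImageGrid(f, init@center)
}

#' MAP-EM reconstruction
#'
#' Multiplicative expectation-maximisation update
#' \deqn{f \leftarrow \frac{f}{A^T 1 + \beta\,L f}\; A^T\!\frac{p}{A f}}
#' with an optional one-step-late quadratic smoothing prior of weight
#' `priorWeight` (`L` is the discrete Laplacian; weight 0, the default,
#' gives plain ML-EM).  Requires a non-negative sinogram and initial
#' image; iterates remain non-negative.
#'
#' @inheritParams sirt
#' @param priorWeight quadratic prior weight beta, >= 0.
#' @return an [ImageGrid-class].
#' @export
mapEM <- function(sino, init, iterations, priorWeight = 0) {
  checkInit(sino, init)
  if (min(sino@data) < 0) stop("mapEM requires a non-negative sinogram")
  if (min(init@pixels) < 0) stop("mapEM requires a non-negative init")
  n <- nrow(init@pixels)
  L <- ncol(sino@data)
  sens <- projectAdjoint(Sinogram(matrix(1, nrow(sino@data), L),
                                  sino@angles, sino@tAxis),
                         n, init@center)@pixels
  lap <- function(m) {
    up <- rbind(m[1, ], m[-nrow(m), ]); dn <- rbind(m[-1, ], m[nrow(m), ])
    lf <- cbind(m[, 1], m[, -ncol(m)]); rt <- cbind(m[, -1], m[, ncol(m)])
    4 * m - up - dn - lf - rt
  }
  f <- init@pixels
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    proj <- forwardProject(ImageGrid(f, init@center), sino@angles,
                           nbins = L)@data
    ratio <- safeDiv(sino@data, proj, eps)
    bp <- projectAdjoint(Sinogram(ratio, sino@angles, sino@tAxis),
                         n, init@center)@pixels
    den <- sens + priorWeight * lap(f)
    f <- f * safeDiv(bp, den, eps)
    f[f < 0] <- 0
  }
  ImageGrid(f, init@center)
}
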