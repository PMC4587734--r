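#' Design the symmetric deconvolution filter F
#'
#' Finds the symmetric \eqn{2n+1}-tap filter minimising
#' \eqn{\|h \otimes F - \delta\|_2^2}, where \eqn{h} is a spatial ramp
#' kernel and \eqn{\delta} the discrete unit impulse, then rescales the
#' solution so its taps sum to 2 (the normalisation under which the filter
#' is conventionally quoted; the scale acts as a relaxation factor when
#' the filter is used inside the correction loop).
#'
#' Two conventions for the convolution in the objective are available:
#' `"linear"` (default) builds the full zero-padded linear-convolution
#' system on \eqn{4n+1} output samples and solves it in the least-squares
#' sense under the symmetry constraint; `"circular"` solves the circular
#' deconvolution on the \eqn{2n+1}-sample support exactly.  The linear
#' convention is the default because it reproduces the conventional
#' normalized coefficients for \eqn{h_5} at DFT length 128.
#'
#' @param h a [RampKernel-class] (or any symmetric odd-length kernel as a
#'   [RampKernel-class]).
#' @param method `"linear"` or `"circular"` (see Details).
#' @return a [CorrectionFilter-class]; `normConstant` holds the applied
#'   scale and `residualNorm` the deconvolution residual of the
#'   unnormalised solution.
#' @examples
#' designFilter(rampKernel(5, 128))
#' @export
designFilter <- function(h, method = c("linear", "circular")) {
  stopifnot(is(h, "RampKernel"))
  method <- match.arg(method)
  taps <- h@taps
  m <- length(taps)
  n <- h@halfWidth
  if (all(taps == 0)) stop("degenerate input: all-zero kernel")

  if (method == "linear") {
    # full linear convolution: (2m - 1) output samples, impulse at center
    A <- matrix(0, 2 * m - 1, m)
    for (j in seq_len(m)) A[j:(j + m - 1), j] <- taps
    d <- numeric(2 * m - 1); d[m] <- 1
    # symmetry constraint: tap j == tap m + 1 - j
    S <- matrix(0, m, n + 1)
    for (j in seq_len(n + 1)) { S[j, j] <- 1; S[m + 1 - j, j] <- 1 }
    S[n + 1, n + 1] <- 1                  # center counted once
    As <- A %*% S
    x <- qr.solve(As, d)
    f <- as.numeric(S %*% x)
  } else {
    # circular deconvolution on the 2n+1 support: circulant solve
    C <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      off <- (i - j) %% m
      o <- if (off <= n) off else off - m
      C[i, j] <- taps[o + n + 1]
    }
    d <- numeric(m); d[n + 1] <- 1
    f <- solve(C, d)
  }
  A <- matrix(0, 2 * m - 1, m)
  for (j in seq_len(m)) A[j:(j + m - 1), j] <- taps
  d <- numeric(2 * m - 1); d[m] <- 1
  resid <- sqrt(sum((as.numeric(A %*% f) - d)^2))
  norm <- 2 / sum(f)
  f <- f * norm
  f <- (f + rev(f)) / 2
  new("CorrectionFilter", taps = f, halfWidth = as.integer(n),
      N = h@N, normConstant = norm, residualNorm = resid)
}

# zero-padded linear convolution, 'same' output length
convolveSame <- function(x, taps) {
  m <- length(taps)
  h <- (m - 1) %/% 2
  y <- stats::convolve(x, rev(taps), type = "open")
  y[(h + 1):(h + length(x))]
}

#' Filter a reprojection residual row
#'
#' Zero-padded linear convolution of the row with the filter taps,
#' returning the central (`same`-length) part.  Residual rows decay to
#' zero at the detector edges (the object lies inside the field of view),
#' so zero padding introduces no boundary artifact.  Linear in the input.
#'
#' @param residual numeric row, or a matrix / [Sinogram-class] filtered
#'   row-wise.
#' @param filt a [CorrectionFilter-class].
#' @return same type as `residual`.
#' @export
filterResidual <- function(residual, filt) {
  stopifnot(is(filt, "CorrectionFilter"))
  taps <- filt@taps
  if (is(residual, "Sinogram")) {
    if (ncol(residual@data) < length(taps))
      stop("row shorter than filter")
    out <- t(apply(residual@data, 1, convolveSame, taps = taps))
    return(Sinogram(out, residual@angles, residual@tAxis))
  }
  if (is.matrix(residual)) {
    if (ncol(residual) < length(taps)) stop("row shorter than filter")
    return(t(apply(residual, 1, convolveSame, taps = taps)))
  }
  if (length(residual) < length(taps)) stop("row shorter than filter")
  convolveSame(residual, taps)
}

#' Iterative FBP with reprojection-residual correction
#'
#' Runs classic FBP, then repeatedly: forward-projects the current
#' estimate along the original angles, takes the residual against the
#' measured sinogram, filters each residual row with the deconvolution
#' filter F ([designFilter()]), reconstructs the filtered residual by FBP
#' and adds the result to the estimate.  The per-stage reprojection
#' mean-squared residual
#' \eqn{s = \frac{1}{LK}\sum_i \|\hat p_i - p_i\|_2^2}
#' is logged at every stage; iteration stops after
#' `cfg@maxIterations` corrections or as soon as the relative improvement
#' of s falls below `cfg@stopTolerance`, and the iterate with the best s
#' is returned.
#'
#' @param sino measured [Sinogram-class].
#' @param cfg a [ReconConfig-class]; `maxIterations = 0` reduces to
#'   classic FBP.
#' @return a list with elements `image` (the best-s [ImageGrid-class]),
#'   `log` (data.frame with columns `iteration` and `s`), and `filter`
#'   (the [CorrectionFilter-class] used, or `NULL` if no iteration ran).
#' @examples
#' ph <- headPhantom(32)
#' sg <- forwardProject(ph, seq(0, 178, by = 2))
#' fit <- iterateFBP(sg, reconConfig(32, maxIterations = 2))
#' fit$log
#' @export
iterateFBP <- function(sino, cfg) {
  stopifnot(is(sino, "Sinogram"), is(cfg, "ReconConfig"))
  P0 <- sino@data
  L <- ncol(P0)
  N <- if (is.na(cfg@fftLength)) defaultFFTLength(L) else cfg@fftLength
  fhat <- fbpReconstruct(sino, cfg)
  filt <- NULL
  if (cfg@maxIterations > 0)
    filt <- designFilter(rampKernel(cfg@filterHalfWidth, N))

  reproject <- function(img) {
    rp <- forwardProject(img, sino@angles, nbins = L)
    if (!identical(dim(rp@data), dim(P0)))
      stop("internal consistency error: reprojection shape mismatch")
    rp@data
  }

  slog <- numeric(0)
  best <- fhat; bestS <- Inf
  for (k in 0:cfg@maxIterations) {
    Phat <- reproject(fhat)
    s <- mean((Phat - P0)^2)
    slog <- c(slog, s)
    if (s < bestS) { bestS <- s; best <- fhat }
    if (k == cfg@maxIterations) break
    if (k > 0) {
      prev <- slog[k]
      if ((prev - s) / prev < cfg@stopTolerance) break
    }
    resid <- filterResidual(P0 - Phat, filt)
    corr <- fbpReconstruct(Sinogram(resid, sino@angles, sino@tAxis), cfg)
    fhat <- ImageGrid(fhat@pixels + corr@pixels, fhat@center)
  }
  list(image = best,
       log = data.frame(iteration = seq_along(slog) - 1L, s = slog),
       filter = filt)
}
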