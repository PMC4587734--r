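asImageMatrix <- function(x) {
  if (is(x, "ImageGrid")) x@pixels else as.matrix(x)
}

#' Pixelwise mean squared error between two images
#'
#' \eqn{MSE(I^r, I^o) = \frac{1}{M}\sum_k (I^r_k - I^o_k)^2} over all M
#' pixels.
#'
#' @param recon,ref [ImageGrid-class] objects or matrices of equal shape.
#' @return numeric(1), >= 0; zero iff the images are identical.
#' @export
imageMSE <- function(recon, ref) {
  a <- asImageMatrix(recon); b <- asImageMatrix(ref)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mean((a - b)^2)
}

#' Global universal quality index (UQI)
#'
#' Product of a structure/contrast term and a luminance term,
#' \deqn{UQI = \frac{2\,Cov(I^r, I^o)}{\sigma_r^2 + \sigma_o^2}\cdot
#'   \frac{2\,\bar I^r \bar I^o}{(\bar I^r)^2 + (\bar I^o)^2},}
#' computed over the whole image, with variances normalised by M and the
#' covariance by M - 1.  Equals 1 for identical non-constant images.
#'
#' @param recon,ref images of equal shape, at least one non-constant.
#' @return numeric(1) in `[-1, 1]` (up to the M/(M-1) covariance factor).
#' @export
uqi <- function(recon, ref) {
  a <- asImageMatrix(recon); b <- asImageMatrix(ref)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  M <- length(a)
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  if (va == 0 && vb == 0) stop("undefined metric: both images constant")
  cv <- sum((a - ma) * (b - mb)) / (M - 1)
  (2 * cv / (va + vb)) * (2 * ma * mb / (ma^2 + mb^2))
}

#' Mutual information between two images
#'
#' Estimated from the joint histogram on an `nBins x nBins` grid of
#' equal-width bins spanning each image's own range, with marginals taken
#' from the same histogram; zero-probability cells contribute zero.
#' Symmetric in its arguments by construction.  Reported in bits
#' (base-2 logarithm).
#'
#' @param recon,ref images of equal shape.
#' @param nBins histogram bin count per axis, integer >= 2 (default 256).
#' @return numeric(1), >= 0.
#' @export
mutualInformation <- function(recon, ref, nBins = 256L) {
  if (length(nBins) != 1L || nBins != round(nBins) || nBins < 2)
    stop("nBins must be an integer >= 2")
  a <- as.vector(asImageMatrix(recon)); b <- as.vector(asImageMatrix(ref))
  if (length(a) != length(b)) stop("shape mismatch")
  nBins <- as.integer(nBins)
  binOf <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    i <- floor((x - r[1]) / (r[2] - r[1]) * nBins) + 1L
    pmin(i, nBins)
  }
  ia <- binOf(a); ib <- binOf(b)
  joint <- table(factor(ia, levels = seq_len(nBins)),
                 factor(ib, levels = seq_len(nBins)))
  p <- joint / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' Reprojection residual statistic (mean squared projection difference)
#'
#' Mean over all K x L sinogram samples of the squared differences,
#' \eqn{s = \frac{1}{LK}\sum_{i=1}^{K} \|p^{test}_i - p^{ref}_i\|_2^2}.
#'
#' @param pRef,pTest [Sinogram-class] objects (or matrices) of equal
#'   shape.
#' @return numeric(1), >= 0.
#' @export
projectionResidualStat <- function(pRef, pTest) {
  a <- if (is(pRef, "Sinogram")) pRef@data else as.matrix(pRef)
  b <- if (is(pTest, "Sinogram")) pTest@data else as.matrix(pTest)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mean((b - a)^2)
}

#' Bundle quality criteria for a reconstruction
#'
#' @param recon,ref images of equal shape.
#' @param nBins mutual-information histogram bins.
#' @param sValues optional per-stage reprojection residuals to attach.
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(recon, ref, nBins = 256L, sValues = numeric(0)) {
  new("QualityReport",
      mse = imageMSE(recon, ref),
      uqi = uqi(recon, ref),
      mi = mutualInformation(recon, ref, nBins),
      sValues = as.numeric(sValues),
      nBins = as.integer(nBins))
}
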