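# TIFF/CSV serialization conventions:
#  - images and sinogram data go to 32-bit float TIFF; TIFF stores
#    [0, 1] floats, so out-of-range data are mapped affinely into [0, 1]
#    and the (offset, scale) pair is recorded in a small sidecar file
#    (`<path>.scale.csv`) which reading inverts.  Data already in [0, 1]
#    are stored unscaled, with no sidecar.
#  - a sinogram's angle list goes to a sidecar CSV (column angle_deg,
#    >= 6 decimals) together with the detector-axis origin and the
#    orientation of the TIFF (angles-as-rows is canonical).

scaleSidecar <- function(path) paste0(path, ".scale.csv")

writeFloatTIFF <- function(m, path) {
  lo <- min(m); hi <- max(m)
  if (lo >= 0 && hi <= 1) {
    if (file.exists(scaleSidecar(path))) unlink(scaleSidecar(path))
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  offset <- lo
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - offset) / scale, path, bits.per.sample = 32L)
  utils::write.csv(data.frame(offset = sprintf("%.17g", offset),
                              scale = sprintf("%.17g", scale)),
                   scaleSidecar(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

readFloatTIFF <- function(path) {
  r <- tiff::readTIFF(path)
  if (length(dim(r)) == 3L) r <- r[, , 1]
  if (file.exists(scaleSidecar(path))) {
    sc <- utils::read.csv(scaleSidecar(path))
    if (!all(c("offset", "scale") %in% names(sc)))
      stop("malformed scale sidecar: ", scaleSidecar(path))
    r <- r * as.numeric(sc$scale[1]) + as.numeric(sc$offset[1])
  }
  r
}

#' Write an ImageGrid to a 32-bit float TIFF
#'
#' Values are stored in single precision; an affine (offset, scale) map
#' into `[0, 1]` is recorded in the TIFF description tag and inverted on
#' read, so a write/read cycle is exact for data already in `[0, 1]` and
#' accurate to single precision otherwise (a second cycle is
#' bit-identical).
#'
#' @param img an [ImageGrid-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeImageTIFF <- function(img, path) {
  stopifnot(is(img, "ImageGrid"))
  writeFloatTIFF(img@pixels, path)
}

#' Read an ImageGrid from TIFF
#'
#' @param path TIFF file written by [writeImageTIFF()] (or any
#'   single-channel TIFF).
#' @param center rotation-center override; default geometric center.
#' @return an [ImageGrid-class].
#' @export
readImageTIFF <- function(path, center = NULL) {
  m <- readFloatTIFF(path)
  if (is.null(center)) center <- (nrow(m) - 1) / 2
  ImageGrid(m, center)
}

#' Write an 8-bit PNG preview of an image
#'
#' Intensities are linearly rescaled to the full grey range; for
#' quantitative storage use [writeImageTIFF()].
#'
#' @param img an [ImageGrid-class] or matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  m <- asImageMatrix(img)
  lo <- min(m); hi <- max(m)
  png::writePNG(if (hi > lo) (m - lo) / (hi - lo) else m * 0, path)
  invisible(path)
}

#' Write a Sinogram as TIFF + angle sidecar CSV
#'
#' The data matrix goes to a 32-bit float TIFF in the canonical
#' angles-as-rows orientation; the sidecar CSV records the angle list in
#' degrees (6 decimals), the detector-axis origin and the orientation
#' flag.
#'
#' @param sino a [Sinogram-class].
#' @param path TIFF path; the sidecar is `paste0(path, ".angles.csv")`
#'   unless `csvPath` is given.
#' @param csvPath optional sidecar path.
#' @return the TIFF path, invisibly.
#' @export
writeSinogram <- function(sino, path, csvPath = paste0(path, ".angles.csv")) {
  stopifnot(is(sino, "Sinogram"))
  writeFloatTIFF(sino@data, path)
  df <- data.frame(angle_deg = sprintf("%.6f", sino@angles))
  df$orientation <- c("angles_as_rows", rep("", nrow(df) - 1L))
  df$t_origin <- c(sprintf("%.6f", sino@tAxis[1]), rep("", nrow(df) - 1L))
  utils::write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Sinogram from TIFF + angle sidecar CSV
#'
#' @param path TIFF path.
#' @param csvPath sidecar CSV path (default `paste0(path, ".angles.csv")`).
#' @param anglesAsRows set `FALSE` if the TIFF stores angles as columns;
#'   the matrix is transposed on read.
#' @return a [Sinogram-class].
#' @export
readSinogram <- function(path, csvPath = paste0(path, ".angles.csv"),
                         anglesAsRows = TRUE) {
  m <- readFloatTIFF(path)
  if (!anglesAsRows) m <- t(m)
  if (!file.exists(csvPath)) stop("missing angle sidecar: ", csvPath)
  df <- tryCatch(utils::read.csv(csvPath, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed angle sidecar: ",
                                          conditionMessage(e)))
  if (!"angle_deg" %in% names(df))
    stop("malformed angle sidecar: no angle_deg column")
  ang <- suppressWarnings(as.numeric(df$angle_deg))
  if (anyNA(ang)) stop("malformed angle sidecar: non-numeric angles")
  if (length(ang) != nrow(m))
    stop("angle count does not match sinogram rows")
  Sinogram(m, ang)
}

#' Flat-/dark-field log normalisation of a raw scan
#'
#' Converts raw detector counts to line integrals per sample:
#' \deqn{p = \log_{10}(p^b - p^d) - \log_{10}(p^o - p^d)}
#' with background (flat) `b`, dark `d` and projection `o` frames.
#' Non-positive differences are clamped to `epsilon` before the
#' logarithm; the number of clamped samples is reported via a message
#' and attached as attribute `clamped` to the result.
#'
#' @param scan a [RawScan-class]; columns are projection vectors.
#' @param epsilon clamp value; default `1e-6 * max(background)`.
#' @param angles optional angle vector (degrees) for the resulting
#'   sinogram; defaults to an even spacing of `[0, 180)` over the
#'   columns.
#' @return a [Sinogram-class] with one row per frame column.
#' @export
preprocessLogNormalize <- function(scan, epsilon = NULL, angles = NULL) {
  stopifnot(is(scan, "RawScan"))
  if (is.null(epsilon)) epsilon <- 1e-6 * max(scan@background)
  if (epsilon <= 0) stop("epsilon must be positive")
  db <- scan@background - scan@dark
  do <- scan@projection - scan@dark
  nClamp <- sum(db < epsilon) + sum(do < epsilon)
  p <- log10(pmax(db, epsilon)) - log10(pmax(do, epsilon))
  if (nClamp > 0)
    message(sprintf("preprocessLogNormalize: clamped %d non-positive samples",
                    nClamp))
  K <- ncol(p)
  if (is.null(angles)) angles <- seq(0, 180, length.out = K + 1)[seq_len(K)]
  out <- Sinogram(t(p), angles)
  attr(out@data, "clamped") <- nClamp
  out
}
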