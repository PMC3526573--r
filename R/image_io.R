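#' Calibration profiles
#'
#' Named table of spatial calibrations (um^2 per pixel) by acquisition
#' profile. Only the 4x objective at 1280x960 is known a priori (2.86
#' um^2/pixel); other optics need a user-supplied calibration.
#'
#' @return named numeric vector of um^2-per-pixel factors.
#' @export
calibrationProfiles <- function() {
  c("4x_1280x960" = 2.86)
}

#' Convert an RGB image to calibrated greyscale
#'
#' Computes a weighted channel average, by default 0.290 R + 0.570 G +
#' 0.140 B. Weights are used exactly as given (no renormalisation) and the
#' result keeps double precision; no re-quantisation takes place. An input
#' that is already single-channel is passed through unchanged.
#'
#' @param img an H x W x 3 numeric array, an H x W matrix (returned
#'   as-is), or a GrayImage (returned as-is).
#' @param weights length-3 non-negative channel weights (R, G, B).
#' @param calibration area per pixel in um^2 attached to the result.
#' @param profile calibration profile name recorded on the result.
#' @return a \linkS4class{GrayImage}.
#' @examples
#' rgb <- array(100, dim = c(4, 4, 3))
#' pixels(toGrayscale(rgb))[1, 1]  # 100: default weights sum to 1
#' @export
toGrayscale <- function(img, weights = c(0.290, 0.570, 0.140),
                        calibration = 2.86, profile = "4x_1280x960") {
  if (is(img, "GrayImage")) return(img)
  if (is.matrix(img))
    return(new("GrayImage", pixels = img, calibration = calibration,
               profile = profile))
  if (!(is.array(img) && length(dim(img)) == 3L))
    stop("expected an H x W x 3 array, an H x W matrix, or a GrayImage")
  if (dim(img)[3L] != 3L)
    stop(sprintf("expected 3 channels, got %d", dim(img)[3L]))
  if (length(weights) != 3L || any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be 3 finite non-negative numbers")
  g <- weights[1L] * img[, , 1L] + weights[2L] * img[, , 2L] +
       weights[3L] * img[, , 3L]
  g <- matrix(g, dim(img)[1L], dim(img)[2L])  # keep 1 x N shapes
  new("GrayImage", pixels = g, calibration = calibration, profile = profile)
}

#' Load a microscopy image
#'
#' Reads a PNG or TIFF file, converts RGB content to greyscale with the
#' standard channel weights, and attaches the spatial calibration from a
#' named profile (or an explicit um^2-per-pixel value). Intensities are
#' kept on the [0, 1] scale the readers return; the texture features
#' downstream are invariant to a global intensity rescaling.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param profile a name from \code{\link{calibrationProfiles}}.
#' @param calibration explicit um^2/pixel, overriding \code{profile}.
#' @param weights greyscale channel weights, see \code{\link{toGrayscale}}.
#' @return a \linkS4class{GrayImage}.
#' @export
loadImage <- function(path, profile = "4x_1280x960", calibration = NULL,
                      weights = c(0.290, 0.570, 0.140)) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' for %s (PNG/TIFF only)",
                 ext, path)))
  if (is.null(calibration)) {
    profs <- calibrationProfiles()
    if (!profile %in% names(profs))
      stop(sprintf(
        "unknown calibration profile '%s'; supply calibration= explicitly",
        profile))
    calibration <- unname(profs[[profile]])
  } else {
    profile <- "custom"
  }
  if (is.array(raw) && length(dim(raw)) == 3L) {
    if (dim(raw)[3L] == 4L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(raw)[3L] == 2L) raw <- raw[, , 1L]                 # grey+alpha
  }
  toGrayscale(raw, weights = weights, calibration = calibration,
              profile = profile)
}

#' Write a greyscale image or binary mask
#'
#' Values are clipped to [0, 1] for storage; masks (0/1 integer matrices)
#' are written as 0/255 8-bit PNG or TIFF.
#'
#' @param img a GrayImage, numeric matrix on [0, 1], or 0/1 mask matrix.
#' @param path output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(img, path) {
  m <- if (is(img, "GrayImage")) pixels(img) else img
  storage <- pmin(pmax(m, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(storage, path),
    tif = ,
    tiff = tiff::writeTIFF(storage, path, bits.per.sample = 16L),
    stop(sprintf("unsupported output format '%s'", ext)))
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Any strictly positive stored intensity counts as foreground.
#'
#' @param path PNG or TIFF path.
#' @return integer 0/1 matrix.
#' @export
loadMask <- function(path) {
  g <- loadImage(path, calibration = 1)
  m <- pixels(g)
  matrix(as.integer(m > 0), nrow(m), ncol(m))
}
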