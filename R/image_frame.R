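#' Calibrated 2D intensity image
#'
#' A thin container pairing a matrix of non-negative pixel intensities with
#' its micrometre-per-pixel calibration. Rows index y (downward), columns
#' index x (rightward); the origin sits at the centre of the top-left pixel,
#' so pixel (i, j) (1-based matrix indices) has physical coordinates
#' `x = (j - 1) * pixel_size_um`, `y = (i - 1) * pixel_size_um`.
#'
#' @param intensities Numeric matrix of non-negative intensities.
#' @param pixel_size_um Calibration in micrometres per pixel (> 0).
#' @return An object of class `image_frame` with elements `intensities`,
#'   `pixel_size_um`, `width_px`, `height_px`, `width_um`, `height_um`.
#' @examples
#' f <- image_frame(matrix(0, 16, 16), pixel_size_um = 0.5)
#' f$width_um
#' @export
image_frame <- function(intensities, pixel_size_um) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  structure(list(
    intensities = intensities,
    pixel_size_um = as.numeric(pixel_size_um),
    width_px = ncol(intensities),
    height_px = nrow(intensities),
    width_um = ncol(intensities) * pixel_size_um,
    height_um = nrow(intensities) * pixel_size_um
  ), class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame: %d x %d px (%.1f x %.1f um at %.4g um/px), range [%.4g, %.4g]\n",
              x$width_px, x$height_px, x$width_um, x$height_um,
              x$pixel_size_um, min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Read a calibrated micrograph from TIFF or PNG
#'
#' Reads a single-channel 8- or 16-bit image and attaches the pixel
#' calibration, which must always be supplied by the caller (it is never
#' guessed from file metadata). Intensities are returned on the integer
#' count scale of the stored bit depth. Multi-page TIFFs and colour images
#' are rejected: the analysis is strictly two-dimensional and
#' single-channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um Calibration in micrometres per pixel.
#' @return An [image_frame()].
#' @export
read_image <- function(path, pixel_size_um) {
  if (missing(pixel_size_um) || is.null(pixel_size_um))
    stop("pixel_size_um calibration is required")
  if (!is.numeric(pixel_size_um) || !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("configuration error: pixel_size_um must be a positive number")
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) > 1)
      stop("multi-page TIFF not supported: the pipeline is 2D-only (", path, ")")
    img <- pages[[1]]
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    img <- img * (2^depth - 1)
  } else {
    stop("unsupported image format '", ext, "': use TIFF or PNG")
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) {
      img <- img[, , 1]
    } else {
      stop("colour (multi-channel) image rejected: supply a single-channel ",
           "grayscale image (", path, ")")
    }
  }
  image_frame(round(unclass(img)), pixel_size_um = pixel_size_um)
}

#' Crop a rectangular region from an image frame
#'
#' Used to emulate a higher magnification by analysing only a central
#' portion of a field. Coordinates are in micrometres in the frame's
#' coordinate system; the crop snaps to whole pixels.
#'
#' @param frame An [image_frame()].
#' @param x0_um,y0_um Top-left corner of the crop, micrometres.
#' @param width_um,height_um Crop extent, micrometres.
#' @return An [image_frame()] whose origin is the crop's top-left pixel.
#' @export
crop_image <- function(frame, x0_um, y0_um, width_um, height_um) {
  stopifnot(inherits(frame, "image_frame"))
  px <- frame$pixel_size_um
  j0 <- max(1L, 1L + as.integer(round(x0_um / px)))
  i0 <- max(1L, 1L + as.integer(round(y0_um / px)))
  j1 <- min(frame$width_px, j0 + as.integer(round(width_um / px)) - 1L)
  i1 <- min(frame$height_px, i0 + as.integer(round(height_um / px)) - 1L)
  if (j1 <= j0 || i1 <= i0) stop("empty crop region")
  image_frame(frame$intensities[i0:i1, j0:j1, drop = FALSE], px)
}
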