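# Raster I/O. Images are handled in-memory as H x W x 3 arrays with 8-bit
# sRGB channel scale [0, 255] (stored as doubles); masks as H x W matrices
# of 0/1.

#' Read an RGB image
#'
#' Reads PNG or TIFF into an `H x W x 3` array on the `[0, 255]` scale.
#' Grayscale images are replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @return `H x W x 3` numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(raw)) == 2) raw <- array(raw, dim = c(dim(raw), 1))
  if (dim(raw)[3] == 1) raw <- raw[, , c(1, 1, 1), drop = FALSE]
  raw[, , 1:3, drop = FALSE] * 255
}

#' Write an RGB image as PNG
#'
#' @param image `H x W x 3` array on the `[0, 255]` scale; values are
#'   clipped into range.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  x <- image / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  png::writePNG(x, path)
  invisible(path)
}

#' Read or write a binary mask as single-channel PNG
#'
#' Masks are stored with 0 = background and 255 = plant/ROI.
#'
#' @param path PNG path.
#' @return `read_mask`: an `H x W` 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1
}

#' @rdname read_mask
#' @param mask `H x W` binary matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}
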