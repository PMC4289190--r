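#' Read a brightfield RGB image
#'
#' Reads an 8-bit PNG or TIFF file into the package's working representation:
#' a numeric `H x W x 3` array of intensities in `[0, 255]`. Grayscale files
#' are replicated over three channels and an alpha channel, if present, is
#' dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric `H x W x 3` array with values in `[0, 255]`.
#' @seealso [write_rgb_image()], [locate_and_crop()]
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    zs_stop(paste0("unsupported image format: ", ext), "zs_parameter_error")
  )
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x <- x * 255
  storage.mode(x) <- "double"
  x
}

#' Write an RGB image array to a PNG file
#'
#' @param img numeric `H x W x 3` array in `[0, 255]`.
#' @param path output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

# validate the RGBImage contract: H x W x 3, H,W >= 64, values in [0,255]
assert_rgb_image <- function(img, min_side = 64) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    zs_stop("image must be an H x W x 3 array", "zs_parameter_error")
  }
  if (d[1] < min_side || d[2] < min_side) {
    zs_stop(sprintf("image must be at least %d x %d pixels", min_side, min_side),
            "zs_parameter_error")
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255) {
    zs_stop("pixel intensities must lie in [0, 255]", "zs_parameter_error")
  }
  invisible(img)
}

# grayscale for localization: unweighted channel mean (larvae are dark on a
# bright background in all three channels)
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}
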