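#' RGB image containers and file I/O
#'
#' Images are plain numeric arrays of dimension height x width x 3 with
#' channel values in `[0, 255]` (8-bit scale, stored as doubles). This keeps
#' the toolkit interoperable with `png`, `tiff` and `EBImage` without copying
#' pixel data into a bespoke class.
#'
#' @param x object to validate or coerce.
#' @return `as_rgb_image()` returns a height x width x 3 numeric array with
#'   values clamped to `[0, 255]`.
#' @export
as_rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop_invalid_input("an RGB image must be a height x width x 3 array")
  if (!is.numeric(x) || anyNA(x))
    stop_invalid_input("RGB image values must be finite numbers")
  x <- pmin(pmax(x, 0), 255)
  storage.mode(x) <- "double"
  x
}

assert_rgb <- function(x, what = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L ||
      !is.numeric(x) || anyNA(x) || min(x) < 0 || max(x) > 255)
    stop_invalid_input(sprintf(
      "%s must be a height x width x 3 numeric array with values in [0, 255]", what))
  invisible(x)
}

# Reproducible half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Per-pixel channel-mean ("grayscale") image
#'
#' The grayscale substrate used by the intensity and contrast metrics: the
#' arithmetic mean of the red, green and blue values at each pixel.
#'
#' @param img RGB image array.
#' @return height x width numeric matrix.
#' @export
gray_mean <- function(img) {
  assert_rgb(img)
  matrix(img[, , 1] + img[, , 2] + img[, , 3], dim(img)[1], dim(img)[2]) / 3
}

#' Read / write 8-bit RGB images (PNG or TIFF)
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_image()` returns an RGB image array on the 0-255 scale.
#'   Grayscale files are replicated to three channels; alpha is dropped.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste("no such image file:", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid_input(paste("unsupported image format:", ext)))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  as_rgb_image(round_half_up(raw * 255))
}

#' @rdname read_image
#' @param img RGB image array to write.
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop_invalid_input(paste("unsupported image format:", ext)))
  invisible(path)
}

# Write / read a ternary label matrix ({0,1,2}) as an indexed 8-bit PNG.
write_label_image <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

read_label_image <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  round_half_up(raw * 255)
}
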