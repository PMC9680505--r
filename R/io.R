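#' Read and write RGB images and class masks as PNG
#'
#' Images are `H x W x 3` arrays on \[0, 1\] (alpha channels are dropped,
#' grayscale is replicated to three channels). Class masks are stored as
#' single-channel 8-bit PNGs holding the raw class codes \{0, 1, 2\};
#' `write_mask_preview_png` additionally writes a colour-coded preview
#' (black background, green and yellow vegetation).
#'
#' @param path PNG file path.
#' @param image `H x W x 3` array on \[0, 1\].
#' @param mask Integer matrix of class codes in \{0, ..., 255\}.
#' @return Readers return the array/matrix; writers return `path`
#'   invisibly.
#' @name png_io
NULL

#' @rdname png_io
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname png_io
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- round(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  if (any(mask < 0 | mask > 255)) stop("mask codes must lie in [0, 255]")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
write_mask_preview_png <- function(mask, path) {
  if (!all(mask %in% 0:2)) stop("preview expects class codes {0, 1, 2}")
  png::writePNG(mask_to_rgb(mask), path)
  invisible(path)
}
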