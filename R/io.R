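#' Read a grayscale image from PNG or TIFF
#'
#' Reads an image file and converts it to integer gray levels at the requested
#' bit depth. Multi-channel images are rejected unless `channel` selects one.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param bit_depth Target bit depth of the returned [gray_image()].
#' @param channel For multi-channel files, the 1-based channel index to use;
#'   `NULL` (default) rejects multi-channel input.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, bit_depth = 8L, channel = NULL) {
  if (!file.exists(path)) pg_error(sprintf("no such image file: %s", path), "pg_io")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pg_error(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext), "pg_io")
  )
  if (length(dim(arr)) == 3L) {
    if (is.null(channel))
      pg_error("multi-channel image; pass `channel` to select one", "pg_bad_input")
    if (channel < 1L || channel > dim(arr)[3L])
      pg_error("channel index out of range", "pg_bad_parameter")
    arr <- arr[, , channel]
  }
  maxlev <- 2L^as.integer(bit_depth) - 1L
  gray_image(matrix(as.integer(round(arr * maxlev)), nrow(arr), ncol(arr)),
             bit_depth = bit_depth)
}

#' Write a binary mask as a PNG
#'
#' Foreground (1) pixels are written as white (255), background as black.
#'
#' @param mask Integer 0/1 matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_binary(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Run-length encode a binary mask
#'
#' Column-major run-length encoding, a compact plain-text representation of a
#' mask: runs of the flattened mask with their values and lengths.
#'
#' @param mask Integer 0/1 matrix.
#' @return Data frame with columns `value` and `length`; attributes `rows` and
#'   `cols` record the mask shape.
#' @export
mask_to_rle <- function(mask) {
  assert_binary(mask)
  r <- rle(as.vector(mask))
  out <- data.frame(value = r$values, length = r$lengths)
  attr(out, "rows") <- nrow(mask)
  attr(out, "cols") <- ncol(mask)
  out
}

#' Decode a run-length encoded mask
#'
#' @param rle_df Data frame from [mask_to_rle()] (or with the same columns).
#' @param rows,cols Mask shape; defaults to the attributes stored by
#'   [mask_to_rle()].
#' @return Integer 0/1 matrix.
#' @export
rle_to_mask <- function(rle_df, rows = attr(rle_df, "rows"),
                        cols = attr(rle_df, "cols")) {
  v <- inverse.rle(structure(list(lengths = rle_df$length, values = rle_df$value),
                             class = "rle"))
  if (length(v) != rows * cols)
    pg_error("run lengths do not match the stated mask shape", "pg_bad_input")
  matrix(as.integer(v), rows, cols)
}
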