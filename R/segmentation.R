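pg_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "phenogrowth_error")))
}

#' Grayscale image container
#'
#' A minimal container for a single-channel intensity image: an integer matrix
#' of gray levels plus the bit depth that defines its level range
#' `[0, 2^bit_depth)`. Rows index the vertical axis (origin top-left, row
#' index increasing downward), columns the horizontal axis.
#'
#' @param pixels Integer (or whole-number numeric) matrix of intensities.
#' @param bit_depth Integer bit depth; all intensities must be `< 2^bit_depth`.
#' @return An object of class `gray_image`: a list with `pixels` (integer
#'   matrix) and `bit_depth`.
#' @examples
#' img <- gray_image(matrix(c(10L, 200L), 2, 2), bit_depth = 8)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) pg_error("`pixels` must be a matrix", "pg_bad_input")
  if (any(pixels != round(pixels)) || any(pixels < 0))
    pg_error("intensities must be non-negative integers", "pg_bad_input")
  bit_depth <- as.integer(bit_depth)
  if (any(pixels >= 2^bit_depth))
    pg_error(sprintf("intensities exceed %d-bit range", bit_depth), "pg_bad_input")
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
                 bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, levels %d..%d>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_gray_image <- function(x, bit_depth = 8L) {
  if (inherits(x, "gray_image")) x else gray_image(x, bit_depth)
}

#' Gray-level histogram of an image
#'
#' Counts pixels at each of the `2^bit_depth` gray levels. Element `i` of the
#' result is the number of pixels at level `i - 1`.
#'
#' @param image A [gray_image()] or integer matrix.
#' @param bit_depth Bit depth used when `image` is a bare matrix.
#' @return Integer vector of length `2^bit_depth`.
#' @export
gray_histogram <- function(image, bit_depth = 8L) {
  img <- as_gray_image(image, bit_depth)
  tabulate(as.vector(img$pixels) + 1L, nbins = 2L^img$bit_depth)
}

#' Otsu threshold from a gray-level histogram
#'
#' Exhaustively scans every candidate level `t` and returns the one that
#' maximizes the between-class variance
#' `sigma_B^2(t) = w0(t) * w1(t) * (mu0(t) - mu1(t))^2`, where class 0 holds
#' the levels below `t` and class 1 the levels at or above `t` (matching the
#' [binarize()] convention that pixels below the threshold are background).
#' Ties are broken toward the lowest maximizing level.
#'
#' @param histogram Per-level pixel counts, element `i` counting level `i - 1`
#'   (as produced by [gray_histogram()]).
#' @return The threshold as an integer gray level.
#' @seealso [segment()] for the full mask pipeline.
#' @examples
#' h <- gray_histogram(gray_image(matrix(c(10L, 10L, 200L, 200L), 2, 2)))
#' otsu_threshold(h)
#' @export
otsu_threshold <- function(histogram) {
  if (any(histogram < 0) || sum(histogram) <= 0)
    pg_error("histogram must hold non-negative counts with a positive total", "pg_bad_input")
  if (sum(histogram > 0) < 2L)
    pg_error("degenerate histogram: all pixels share one gray level, no foreground/background split exists",
             "pg_degenerate_histogram")
  levels <- seq_along(histogram) - 1L
  n <- sum(histogram)
  p <- histogram / n
  # cumulative weight and mean of class 0 = {levels < t} for t = 1..L-1
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * levels)
  mu_total <- mu_cum[length(mu_cum)]
  # candidate thresholds t: class0 levels 0..t-1, class1 levels t..L-1
  t_cand <- levels[-1L]                 # 1 .. L-1
  w0_t <- w0[t_cand]                    # weight of levels < t
  w1_t <- 1 - w0_t
  mu0_t <- mu_cum[t_cand] / w0_t
  mu1_t <- (mu_total - mu_cum[t_cand]) / w1_t
  sigma_b <- w0_t * w1_t * (mu0_t - mu1_t)^2
  sigma_b[!is.finite(sigma_b)] <- -Inf  # empty class: not a valid split
  t_cand[which.max(sigma_b)]            # which.max -> first (lowest) maximizer
}

#' Binarize an image at a threshold
#'
#' Pixels with values smaller than the threshold become background (0); all
#' other pixels are assigned to the plant (1).
#'
#' @param image A [gray_image()] or integer matrix.
#' @param threshold Gray level in `[0, 2^bit_depth)`.
#' @param bit_depth Bit depth used when `image` is a bare matrix.
#' @return Integer 0/1 matrix with the shape of `image`.
#' @export
binarize <- function(image, threshold, bit_depth = 8L) {
  img <- as_gray_image(image, bit_depth)
  if (threshold < 0 || threshold >= 2^img$bit_depth)
    pg_error("threshold outside the representable gray-level range", "pg_bad_parameter")
  mask <- (img$pixels >= threshold) * 1L
  matrix(as.integer(mask), nrow(img$pixels), ncol(img$pixels))
}

#' Morphological cleanup configuration
#'
#' Disc-shaped structuring elements for the opening and closing passes that
#' follow binarization. Radius 0 disables a pass.
#'
#' @param opening_radius Disc radius (pixels) for the opening pass.
#' @param closing_radius Disc radius (pixels) for the closing pass.
#' @param keep_largest If `TRUE`, retain only the largest connected foreground
#'   component after morphology. Off by default.
#' @return A `morphology_config` list.
#' @export
morphology_config <- function(opening_radius = 1L, closing_radius = 1L,
                              keep_largest = FALSE) {
  opening_radius <- as.integer(opening_radius)
  closing_radius <- as.integer(closing_radius)
  if (opening_radius < 0 || closing_radius < 0)
    pg_error("morphology radii must be non-negative", "pg_bad_parameter")
  structure(list(opening_radius = opening_radius,
                 closing_radius = closing_radius,
                 keep_largest = isTRUE(keep_largest)),
            class = "morphology_config")
}

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

assert_binary <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    pg_error("mask must be a 0/1 matrix", "pg_bad_input")
}

#' Clean a binary mask by opening then closing
#'
#' Applies a morphological opening (erosion then dilation; removes isolated
#' speckle smaller than the disc) followed by a closing (dilation then
#' erosion; fills pinholes), each with a disc structuring element.
#'
#' @param mask Integer 0/1 matrix, 1 = plant.
#' @param cfg A [morphology_config()].
#' @return Cleaned 0/1 matrix of the same shape.
#' @export
clean_mask <- function(mask, cfg = morphology_config()) {
  assert_binary(mask)
  out <- mask
  if (cfg$opening_radius > 0L && any(out == 1L))
    out <- EBImage::opening(out, disc_brush(cfg$opening_radius))
  if (cfg$closing_radius > 0L && any(out == 1L))
    out <- EBImage::closing(out, disc_brush(cfg$closing_radius))
  out <- matrix(as.integer(as.matrix(out) > 0.5), nrow(mask), ncol(mask))
  if (cfg$keep_largest && any(out == 1L)) out <- keep_largest_component(out)
  out
}

#' Keep only the largest connected foreground component
#'
#' @param mask Integer 0/1 matrix.
#' @return 0/1 matrix retaining the largest 4/8-connected component (EBImage
#'   labelling); the input mask if it is empty.
#' @export
keep_largest_component <- function(mask) {
  assert_binary(mask)
  if (!any(mask == 1L)) return(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
}

#' Segment a plant silhouette from a grayscale image
#'
#' The full mask pipeline: Otsu threshold on the image's gray-level histogram,
#' binarization (pixels below the threshold are background), then
#' morphological opening and closing to remove noise.
#'
#' @param image A [gray_image()] or integer matrix.
#' @param cfg A [morphology_config()].
#' @param bit_depth Bit depth used when `image` is a bare matrix.
#' @return Integer 0/1 matrix, 1 = plant.
#' @examples
#' px <- matrix(30L, 40, 40); px[10:30, 15:25] <- 200L
#' mask <- segment(gray_image(px))
#' sum(mask)
#' @export
segment <- function(image, cfg = morphology_config(), bit_depth = 8L) {
  img <- as_gray_image(image, bit_depth)
  thr <- otsu_threshold(gray_histogram(img))
  clean_mask(binarize(img, thr), cfg)
}
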