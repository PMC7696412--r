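#' Side-projected area of a mask, in pixels
#'
#' The silhouette area seen from the side: the sum of foreground pixels in the
#' binary mask.
#'
#' @param mask Integer 0/1 matrix, 1 = plant.
#' @return Non-negative integer pixel count (0 for an empty mask).
#' @export
side_projected_area <- function(mask) {
  assert_binary(mask)
  sum(mask)
}

#' Bounding extent of the plant silhouette
#'
#' Height and width of the axis-aligned rectangle enclosing the foreground,
#' as inclusive pixel extents. Height is the vertical (row) extent.
#'
#' @param mask Integer 0/1 matrix with at least one foreground pixel.
#' @return Named integer vector `c(height_px, width_px)`.
#' @export
bounding_extent <- function(mask) {
  assert_binary(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    pg_error("empty mask: no plant pixels to enclose", "pg_empty_plant")
  c(height_px = diff(range(idx[, 1L])) + 1L,
    width_px = diff(range(idx[, 2L])) + 1L)
}

#' Pixel-to-physical calibration
#'
#' A single scalar scale factor for a fixed camera geometry: lengths multiply
#' by `scale`, areas by `scale^2`.
#'
#' @param scale Millimetres per pixel, finite and positive.
#' @return A `calibration` list.
#' @export
calibration <- function(scale) {
  if (!is.finite(scale) || scale <= 0)
    pg_error("calibration scale must be finite and positive", "pg_bad_parameter")
  structure(list(scale = scale), class = "calibration")
}

#' Measure silhouette geometry from a mask
#'
#' Extracts pixel-level geometry (area, bounding height and width) and, when a
#' calibration is given, the corresponding physical quantities.
#'
#' @param mask Integer 0/1 matrix.
#' @param cal A [calibration()], or `NULL` to report pixels only.
#' @param angle_deg Optional view angle (degrees) recorded alongside.
#' @return One-row data frame with columns `angle_deg`, `spa_px`, `height_px`,
#'   `width_px` and, if calibrated, `spa_mm2`, `height_mm`, `width_mm`.
#' @export
measure_geometry <- function(mask, cal = NULL, angle_deg = NA_real_) {
  spa <- side_projected_area(mask)
  if (spa > 0L) {
    ext <- bounding_extent(mask)
  } else {
    ext <- c(height_px = 0L, width_px = 0L)
  }
  geom <- data.frame(angle_deg = angle_deg, spa_px = spa,
                     height_px = unname(ext[1L]), width_px = unname(ext[2L]))
  if (!is.null(cal)) geom <- calibrate(geom, cal)
  geom
}

#' Convert pixel geometry to physical units
#'
#' @param geom Data frame with `spa_px`, `height_px`, `width_px` columns (as
#'   from [measure_geometry()]).
#' @param cal A [calibration()].
#' @return `geom` with `spa_mm2`, `height_mm` and `width_mm` columns filled
#'   (areas scale quadratically, lengths linearly).
#' @export
calibrate <- function(geom, cal) {
  if (!inherits(cal, "calibration")) cal <- calibration(cal)
  geom$spa_mm2 <- geom$spa_px * cal$scale^2
  geom$height_mm <- geom$height_px * cal$scale
  geom$width_mm <- geom$width_px * cal$scale
  geom
}

#' Aggregate side-projected area over rotational views
#'
#' One plant is imaged from several azimuthal angles (12 views at 30 degree
#' steps in the standard protocol); its SPA is the arithmetic mean over the
#' views. A warning (not an error) is raised when the number of views differs
#' from `expected_views`, so partial series still aggregate.
#'
#' @param views Numeric vector of per-view SPA values, or a data frame with an
#'   `spa_mm2` (preferred) or `spa_px` column.
#' @param expected_views Number of views the protocol prescribes (default 12).
#' @return The mean SPA, with attribute `n_views`.
#' @export
aggregate_angles <- function(views, expected_views = 12L) {
  if (is.data.frame(views)) {
    col <- if ("spa_mm2" %in% names(views)) "spa_mm2" else "spa_px"
    views <- views[[col]]
  }
  if (length(views) == 0L)
    pg_error("no views to aggregate", "pg_bad_parameter")
  if (length(views) != expected_views)
    warning(sprintf("aggregating %d views (expected %d)", length(views), expected_views),
            call. = FALSE)
  structure(mean(views), n_views = length(views))
}
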