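#' Geometry of the tiltable shuttle track
#'
#' Describes the 120 x 24 cm shuttle box, its central running region of
#' interest (ROI) and the spatial grids used by the rate-map stages. The two
#' reward endzones occupy the ends of the long axis; everything between their
#' boundaries (103 cm by default) is the running ROI and all spatial analysis
#' is restricted to it. Coordinates are in cm with the origin at the
#' ground-level (pivot-end) corner: `x` runs along the long axis (0-120,
#' south = 0, north = 120) and `y` along the short axis (0-24).
#'
#' Fine-grid bins are `bin_side_cm` x `bin_side_cm` squares (2.5 cm default)
#' anchored at the ROI origin and half-open, `[k*2.5, (k+1)*2.5)`. The ROI is
#' not an exact multiple of 2.5 cm, so the residual sliver at the far edge of
#' each axis is folded into the last bin, giving a 9 x 41 grid
#' (short x long axis). The coarse grid used for phase-precession field
#' detection divides the same ROI into 4 x 20 bins.
#'
#' @param long_axis_cm Length of the box along the running axis (cm).
#' @param short_axis_cm Width of the box (cm).
#' @param roi_long_cm Length of the running ROI between the endzone
#'   boundaries (cm). The two endzones share the remainder equally.
#' @param bin_side_cm Side length of a fine-grid bin (cm).
#' @param pivot_end Which end of the box stays on the ground when the box is
#'   tilted (`"south"` = x of 0, `"north"` = x of 120).
#' @return An object of class `track_geometry`.
#' @examples
#' g <- track_geometry()
#' g$n_bins_long   # 41 bins along the running ROI
#' @export
track_geometry <- function(long_axis_cm = 120, short_axis_cm = 24,
                           roi_long_cm = 103, bin_side_cm = 2.5,
                           pivot_end = c("south", "north")) {
  pivot_end <- match.arg(pivot_end)
  stopifnot(long_axis_cm > 0, short_axis_cm > 0, bin_side_cm > 0,
            roi_long_cm > 0, roi_long_cm < long_axis_cm)
  endzone_cm <- (long_axis_cm - roi_long_cm) / 2
  g <- list(
    long_axis_cm  = long_axis_cm,
    short_axis_cm = short_axis_cm,
    roi_long_cm   = roi_long_cm,
    endzone_cm    = endzone_cm,
    bin_side_cm   = bin_side_cm,
    pivot_end     = pivot_end,
    roi_min_cm    = endzone_cm,
    roi_max_cm    = endzone_cm + roi_long_cm,
    n_bins_long   = max(1L, floor(roi_long_cm / bin_side_cm)),
    n_bins_short  = max(1L, floor(short_axis_cm / bin_side_cm)),
    coarse_long   = 20L,
    coarse_short  = 4L
  )
  class(g) <- "track_geometry"
  g
}

#' @export
print.track_geometry <- function(x, ...) {
  cat(sprintf("<track_geometry> %g x %g cm box, %g cm running ROI ",
              x$long_axis_cm, x$short_axis_cm, x$roi_long_cm))
  cat(sprintf("(endzones %g cm), %g cm bins (%d x %d grid), pivot %s\n",
              x$endzone_cm, x$bin_side_cm, x$n_bins_short, x$n_bins_long,
              x$pivot_end))
  invisible(x)
}

# TRUE for samples inside the running ROI along the long axis
in_roi <- function(x, geometry) {
  x >= geometry$roi_min_cm & x < geometry$roi_max_cm
}

# ROI-local long-axis coordinate (0 at the pivot-side endzone boundary)
roi_x <- function(x, geometry) x - geometry$roi_min_cm

# Fine-grid bin indices for ROI samples. Returns a list(ix, iy) of 1-based
# column (long axis) and row (short axis) indices; NA outside the ROI or box.
fine_bin_index <- function(x, y, geometry) {
  xr <- roi_x(x, geometry)
  ok <- in_roi(x, geometry) & y >= 0 & y <= geometry$short_axis_cm
  ix <- ifelse(ok, pmin(floor(xr / geometry$bin_side_cm),
                        geometry$n_bins_long - 1L) + 1L, NA_integer_)
  iy <- ifelse(ok, pmin(floor(y / geometry$bin_side_cm),
                        geometry$n_bins_short - 1L) + 1L, NA_integer_)
  list(ix = as.integer(ix), iy = as.integer(iy))
}

# Coarse-grid (4 x 20 over the ROI) bin indices, same conventions as above.
coarse_bin_index <- function(x, y, geometry) {
  xr <- roi_x(x, geometry)
  ok <- in_roi(x, geometry) & y >= 0 & y <= geometry$short_axis_cm
  wx <- geometry$roi_long_cm / geometry$coarse_long
  wy <- geometry$short_axis_cm / geometry$coarse_short
  ix <- ifelse(ok, pmin(floor(xr / wx), geometry$coarse_long - 1L) + 1L,
               NA_integer_)
  iy <- ifelse(ok, pmin(floor(y / wy), geometry$coarse_short - 1L) + 1L,
               NA_integer_)
  list(ix = as.integer(ix), iy = as.integer(iy))
}

# Centre (cm, ROI-local) of fine-grid long-axis bin k
fine_bin_centre <- function(k, geometry) (k - 0.5) * geometry$bin_side_cm

# End labels ("south" = x 0, "north" = x long_axis) and their x positions
end_x <- function(end, geometry) {
  ifelse(end == "south", 0, geometry$long_axis_cm)
}

opposite_end <- function(end) ifelse(end == "south", "north", "south")
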