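# Rasterized lookup tables: the five per-cell Voronoi factors painted onto
# a shared pixel grid over the normalized flood-map square.

lut_pixel_centers <- function(grid_n) {
  seq(-1 + 1 / grid_n, 1 - 1 / grid_n, length.out = grid_n)
}

#' Rasterize the five Voronoi factors into lookup tables
#'
#' Paints the per-cell factors onto an `grid_n` x `grid_n` pixel grid over
#' `[-1, 1]^2`: each pixel centre receives the factors of its nearest
#' centroid, producing the five LUTs (X, Y, DOI1, DOI2, Energy) that are
#' applied event by event.
#'
#' @param factors A [voronoi_factors()] table.
#' @param calmap The `calibration_map` whose centroids generate the
#'   partition.
#' @param grid_n Pixels per side (>= 2); default 500.
#' @param detector_id Identifier stored in the LUT metadata.
#' @return A `lut_set`: list of five `grid_n` x `grid_n` matrices (`x`,
#'   `y`, `doi1`, `doi2`, `energy`; rows index the x pixel, columns the y
#'   pixel), plus pixel centres, the central-cell photopeak
#'   (`central_peak`), the generating centroids, and metadata.
#' @export
rasterize_luts <- function(factors, calmap, grid_n = 500,
                           detector_id = NULL) {
  if (grid_n < 2) abort("`grid_n` must be at least 2.")
  part <- build_voronoi(calmap)
  ctr <- lut_pixel_centers(grid_n)
  px <- rep(ctr, times = grid_n)      # x varies within a column block? see below
  py <- rep(ctr, each = grid_n)
  # pixel (ix, iy) stored at matrix[ix, iy]: x index fastest (column-major)
  cell <- part$cell(px, py)
  shape <- function(v) matrix(v[cell], grid_n, grid_n)
  central <- attr(factors, "central_cell") %||% which.min(
    factors$node_i^2 + factors$node_j^2)
  structure(list(
    x = shape(factors$f_x),
    y = shape(factors$f_y),
    doi1 = shape(factors$f_doi1),
    doi2 = shape(factors$f_doi2),
    energy = shape(factors$f_e),
    grid_n = as.integer(grid_n),
    pixel_centers = ctr,
    centroids = part$centroids,
    central_peak = factors$f_e[central],
    detector_id = detector_id %||% "unknown",
    provenance = "normal"
  ), class = "lut_set")
}

#' @export
print.lut_set <- function(x, ...) {
  cat(sprintf("<lut_set %s: 5 tables %d x %d, central peak %.0f ch, %s>\n",
              x$detector_id, x$grid_n, x$grid_n, x$central_peak,
              x$provenance))
  invisible(x)
}

#' @rdname rasterize_luts
#' @param x A `lut_set`.
#' @param ... Unused.
#' @export
tidy.lut_set <- function(x, ...) {
  df <- tidyr::expand_grid(iy = seq_len(x$grid_n), ix = seq_len(x$grid_n))
  tibble::tibble(
    x = x$pixel_centers[df$ix], y = x$pixel_centers[df$iy],
    lut_x = x$x[cbind(df$ix, df$iy)],
    lut_y = x$y[cbind(df$ix, df$iy)],
    lut_doi1 = x$doi1[cbind(df$ix, df$iy)],
    lut_doi2 = x$doi2[cbind(df$ix, df$iy)],
    lut_energy = x$energy[cbind(df$ix, df$iy)])
}

#' @rdname rasterize_luts
#' @param object A `lut_set`.
#' @export
autoplot.lut_set <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), dplyr::starts_with("lut_"),
                              names_to = "table", names_prefix = "lut_",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~table, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (normalized)", y = "y (normalized)")
}

# Pixel indices of normalized coordinates; values outside [-1, 1] clamp to
# the border pixel.
lut_pixel_index <- function(v, grid_n) {
  pmin(pmax(ceiling((v + 1) / 2 * grid_n), 1L), grid_n)
}

#' Look up LUT values at event positions
#'
#' @param luts A `lut_set`.
#' @param x_norm,y_norm Normalized event coordinates.
#' @return Tibble with the five factor values per event and a `flagged`
#'   column marking events outside `[-1, 1]^2` (clamped to the border).
#' @export
lut_lookup <- function(luts, x_norm, y_norm) {
  ix <- lut_pixel_index(x_norm, luts$grid_n)
  iy <- lut_pixel_index(y_norm, luts$grid_n)
  id <- cbind(ix, iy)
  tibble::tibble(
    lut_x = luts$x[id], lut_y = luts$y[id],
    lut_doi1 = luts$doi1[id], lut_doi2 = luts$doi2[id],
    lut_energy = luts$energy[id],
    flagged = abs(x_norm) > 1 | abs(y_norm) > 1)
}

#' Calibrate events with a set of lookup tables
#'
#' Applies the five LUTs event by event: planar position is corrected
#' additively in normalized units and scaled to millimetres, energy is
#' scaled by the ratio of the central-cell photopeak to the cell photopeak,
#' and the raw `E/Imax` statistic is mapped to millimetres of DOI between
#' the cell's two DOI factors.
#'
#' @param estimates Event estimates with `x_norm`, `y_norm`, `E_channels`,
#'   `doi_raw`.
#' @param luts A `lut_set`.
#' @param half_size_mm Crystal half-size (normalized-to-mm scale).
#' @param thickness_mm Crystal thickness (mm).
#' @return The input with calibrated columns `x_cal_mm`, `y_cal_mm`,
#'   `E_cal`, `doi_cal_mm` and `flagged` appended (truth columns such as
#'   `x_mm` are left untouched).  The number of events is never changed by
#'   calibration.
#' @export
calibrate_events <- function(estimates, luts, half_size_mm = 25,
                             thickness_mm = 15) {
  stopifnot(inherits(luts, "lut_set"))
  if (is.null(luts$x) || length(luts$x) == 0) abort("empty LUT set.")
  lk <- lut_lookup(luts, estimates$x_norm, estimates$y_norm)
  dplyr::mutate(
    tibble::as_tibble(estimates),
    x_cal_mm = (estimates$x_norm + lk$lut_x) * half_size_mm,
    y_cal_mm = (estimates$y_norm + lk$lut_y) * half_size_mm,
    E_cal = estimates$E_channels * luts$central_peak / lk$lut_energy,
    doi_cal_mm = calibrate_doi(estimates$doi_raw, lk$lut_doi1, lk$lut_doi2,
                               thickness_mm),
    flagged = lk$flagged)
}
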