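#' Full per-detector ("Normal") Voronoi calibration
#'
#' Runs the standard single-detector calibration chain on a collimated
#' source-array acquisition: locate the 121 measured centroids, build the
#' Voronoi partition, extract the five per-cell factors, and rasterize the
#' five lookup tables.
#'
#' @param estimates Event estimates of the calibration acquisition
#'   (`estimate_events()` output); raw event tables are estimated
#'   automatically.
#' @param grid The acquired [source_grid()].
#' @param grid_n LUT pixels per side.
#' @param min_events Minimum events per node/cell.
#' @param make_luts Rasterize the LUTs (`FALSE` returns map + factors only,
#'   which is all the correlation-factor evaluation needs).
#' @param stat_radius Passed to [voronoi_factors()].
#' @param detector_id Identifier; defaults to the event table's.
#' @return A `voronoi_calibration`: list with `$map` (calibration map),
#'   `$factors` (the five per-cell factors) and `$luts` (or `NULL`).
#' @export
#' @examples
#' \donttest{
#' cfg <- detector_config()
#' ev <- simulate_grid_acquisition(source_grid(), 80, cfg, seed = 1)
#' cal <- normal_calibrate(estimate_events(ev), source_grid(), grid_n = 100)
#' }
normal_calibrate <- function(estimates, grid, grid_n = 500, min_events = 30,
                             make_luts = TRUE, stat_radius = c(Inf, 0.08),
                             detector_id = NULL) {
  if (!"x_norm" %in% names(estimates)) {
    estimates <- estimate_events(estimates)
  }
  detector_id <- detector_id %||%
    (if ("detector_id" %in% names(estimates)) estimates$detector_id[1] else "unknown")
  calmap <- localize_sources(estimates, grid,
                             min_events = min(min_events, 50))
  factors <- voronoi_factors(estimates, calmap, min_events = min_events,
                             stat_radius = stat_radius)
  luts <- if (make_luts) {
    rasterize_luts(factors, calmap, grid_n, detector_id)
  }
  structure(list(map = calmap, factors = factors, luts = luts,
                 detector_id = detector_id),
            class = "voronoi_calibration")
}

#' @export
print.voronoi_calibration <- function(x, ...) {
  cat(sprintf("<voronoi_calibration %s: %d cells%s>\n", x$detector_id,
              nrow(x$factors),
              if (is.null(x$luts)) "" else
                sprintf(", LUTs %d x %d", x$luts$grid_n, x$luts$grid_n)))
  invisible(x)
}

#' @rdname normal_calibrate
#' @param x A `voronoi_calibration`.
#' @param ... Unused.
#' @export
tidy.voronoi_calibration <- function(x, ...) {
  tibble::as_tibble(x$factors)
}

#' @rdname normal_calibrate
#' @export
glance.voronoi_calibration <- function(x, ...) {
  tibble::tibble(
    detector_id = x$detector_id,
    n_cells = nrow(x$factors),
    n_events = sum(x$map$nodes$n_events),
    converged = isTRUE(x$map$converged),
    mean_abs_f_x = mean(abs(x$factors$f_x)),
    mean_abs_f_y = mean(abs(x$factors$f_y)),
    central_peak = x$factors$f_e[attr(x$factors, "central_cell") %||%
                                   which.min(x$factors$node_i^2 + x$factors$node_j^2)],
    doi1_mean = mean(x$factors$f_doi1),
    doi2_mean = mean(x$factors$f_doi2),
    n_fallback = attr(x$factors, "n_fallback") %||% NA_integer_)
}
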