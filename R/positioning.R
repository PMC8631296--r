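# Event-level estimators: squared-weight centre of gravity for the planar
# coordinates, energy as the channel sum, raw DOI as E / Imax.

signal_matrix <- function(events, cfg_or_n, axis = c("cols", "rows")) {
  axis <- match.arg(axis)
  n <- if (inherits(cfg_or_n, "detector_config")) cfg_or_n$n_sensors else cfg_or_n
  prefix <- if (axis == "cols") "col" else "row"
  cols <- sprintf("%s_%02d", prefix, seq_len(n))
  if (!all(cols %in% names(events))) {
    abort(sprintf("event table lacks %s signal columns (%s..).", axis, cols[1]))
  }
  as.matrix(events[cols])
}

#' Squared-weight centre-of-gravity planar position
#'
#' The centre-of-gravity estimator with the row and column signals raised to
#' the power of 2, which reduces the compression non-linearity of plain
#' Anger positioning near the crystal edges.  Sensor positions are taken
#' evenly spaced on the normalized axis `[-1, 1]`, so the returned
#' coordinates live in the flood-map frame.
#'
#' @param events Event data frame with `row_*` / `col_*` signal columns
#'   (one event per row), e.g. from [simulate_events()].
#' @param n_sensors Sensors per side (signal columns per axis).
#' @return Tibble with `x_norm` (from columns) and `y_norm` (from rows);
#'   `NA` for events whose signals are all zero on an axis.
#' @export
#' @examples
#' ev <- tibble::tibble(!!!setNames(as.list(rep(1, 24)),
#'   c(sprintf("row_%02d", 1:12), sprintf("col_%02d", 1:12))))
#' cog2_position(ev)   # symmetric pattern -> (0, 0)
cog2_position <- function(events, n_sensors = 12) {
  cols2 <- signal_matrix(events, n_sensors, "cols")^2
  rows2 <- signal_matrix(events, n_sensors, "rows")^2
  p <- seq(-1, 1, length.out = n_sensors)
  sx <- rowSums(cols2)
  sy <- rowSums(rows2)
  tibble::tibble(
    x_norm = ifelse(sx > 0, as.vector(cols2 %*% p) / sx, NA_real_),
    y_norm = ifelse(sy > 0, as.vector(rows2 %*% p) / sy, NA_real_))
}

#' Energy and light-peak statistic of each event
#'
#' Energy is the sum of the signals along one readout axis and `Imax` the
#' maximum along the same axis; their ratio `E / Imax` is the raw
#' depth-of-interaction statistic (a broad light distribution -- shallow
#' interaction -- gives a large ratio; a peaked one a ratio near 1).
#'
#' @inheritParams cog2_position
#' @param axis Which readout axis to use, `"cols"` (default) or `"rows"`.
#' @return Tibble with `E_channels`, `Imax_channels`, `doi_raw`.
#' @export
energy_imax <- function(events, axis = c("cols", "rows"), n_sensors = 12) {
  axis <- match.arg(axis)
  sig <- signal_matrix(events, n_sensors, axis)
  if (any(sig < 0)) abort("signals must be non-negative.")
  e <- rowSums(sig)
  imax <- do.call(pmax, as.data.frame(sig))
  tibble::tibble(
    E_channels = e,
    Imax_channels = imax,
    doi_raw = ifelse(imax > 0, e / imax, NA_real_))
}

#' Estimate position, energy and raw DOI for an event table
#'
#' Applies [cog2_position()] and [energy_imax()] to every event, preserving
#' row order.  Degenerate events (all-zero signals) are dropped with a
#' message rather than an error.
#'
#' @inheritParams energy_imax
#' @return The input tibble with `x_norm`, `y_norm`, `E_channels`,
#'   `Imax_channels`, `doi_raw` appended and degenerate rows removed.
#' @export
#' @examples
#' cfg <- detector_config()
#' ev <- simulate_uniform_acquisition(100, cfg, seed = 1)
#' est <- estimate_events(ev)
estimate_events <- function(events, axis = c("cols", "rows"), n_sensors = 12) {
  out <- dplyr::bind_cols(
    tibble::as_tibble(events),
    cog2_position(events, n_sensors),
    energy_imax(events, axis, n_sensors))
  bad <- !complete.cases(out[c("x_norm", "y_norm", "doi_raw")])
  if (any(bad)) {
    inform(sprintf("dropped %d degenerate event(s) with all-zero signals.",
                   sum(bad)))
    out <- out[!bad, ]
  }
  out
}

#' 2-D flood histogram of estimated planar positions
#'
#' @param estimates Data frame with `x_norm`, `y_norm` (from
#'   [estimate_events()]).
#' @param bins Bins per axis over `[-1, 1]`.
#' @return A `flood_hist`: list with `counts` (bins x bins matrix, rows = x
#'   bin, columns = y bin), `x_centers`, `y_centers`.
#' @export
flood_histogram <- function(estimates, bins = 256) {
  brk <- seq(-1, 1, length.out = bins + 1)
  ix <- pmin(pmax(findInterval(estimates$x_norm, brk, all.inside = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(estimates$y_norm, brk, all.inside = TRUE), 1), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  ctr <- (brk[-1] + brk[-length(brk)]) / 2
  structure(list(counts = counts, x_centers = ctr, y_centers = ctr),
            class = "flood_hist")
}

#' @export
print.flood_hist <- function(x, ...) {
  cat(sprintf("<flood_hist %d x %d bins, %d events>\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @rdname flood_histogram
#' @param object A `flood_hist`.
#' @param ... Unused.
#' @export
autoplot.flood_hist <- function(object, ...) {
  df <- tidyr::expand_grid(x = object$x_centers, y = object$y_centers)
  df$count <- as.vector(t(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (normalized)", y = "y (normalized)", fill = "counts")
}
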