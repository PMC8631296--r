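# The calibration map: measured flood-map centroids of the 11 x 11 source
# array, indexed by mechanical grid node.

new_calibration_map <- function(nodes, grid, converged = TRUE, iterations = NA) {
  stopifnot(all(c("node_i", "node_j", "mech_x", "mech_y", "x", "y",
                  "n_events") %in% names(nodes)))
  structure(list(nodes = tibble::as_tibble(nodes), grid = grid,
                 converged = converged, iterations = iterations),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map %d nodes, %d events%s>\n",
              nrow(x$nodes), sum(x$nodes$n_events),
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' @rdname localize_sources
#' @param x A `calibration_map`.
#' @param ... Unused.
#' @export
tidy.calibration_map <- function(x, ...) x$nodes

# Nearest-centroid index for a set of points, ties broken by the lowest
# cell index.  Loops over centroids so memory stays O(n_points).
nearest_cell <- function(px, py, cx, cy) {
  best <- rep(1L, length(px))
  bestd <- (px - cx[1])^2 + (py - cy[1])^2
  for (k in seq_along(cx)[-1]) {
    d <- (px - cx[k])^2 + (py - cy[k])^2
    upd <- d < bestd          # strict: first (lowest) index wins ties
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  best
}

# Per-axis seeding of the Lloyd iteration: split the marginal distribution
# of measured coordinates into n equal-mass bins and use the bin means as
# cluster centres.  This absorbs both the global affine scale and the
# smooth edge compression of COG^2 positioning without an explicit model.
marginal_seed <- function(values, n) {
  qs <- quantile(values, probs = seq(0, 1, length.out = n + 1), names = FALSE)
  bin <- pmin(pmax(findInterval(values, qs, all.inside = TRUE), 1), n)
  as.vector(tapply(values, factor(bin, levels = seq_len(n)), mean))
}

#' Locate the measured source centroids of a calibration acquisition
#'
#' Builds the calibration map: the 121 measured flood-map positions of the
#' collimated source array.  Centroids are seeded from an equal-mass
#' quantile split of the two marginal coordinate distributions (which
#' follows the global scale and edge compression of the flood map) and
#' refined by Lloyd iterations: assign every event to its nearest centroid,
#' replace each centroid by the mean of its events, repeat until the
#' largest centroid move falls below `tol` or `max_iter` is reached.
#'
#' @param estimates Event estimates (with `x_norm`, `y_norm`) from a
#'   calibration acquisition, e.g. `estimate_events(simulate_grid_acquisition(...))`.
#' @param grid The [source_grid()] that was acquired.
#' @param min_events Minimum events per node; fewer is an error naming the
#'   starved node(s).
#' @param tol Convergence threshold on the largest centroid move
#'   (normalized units).
#' @param max_iter Maximum Lloyd iterations (warning on non-convergence).
#' @param half_size_mm Crystal half-size used to normalize mechanical
#'   positions.
#' @return A `calibration_map` with one row per mechanical node: measured
#'   centroid (`x`, `y`), mechanical position (`mech_x`, `mech_y`,
#'   normalized), and per-node event counts.
#' @export
localize_sources <- function(estimates, grid, min_events = 50,
                             tol = 1e-4, max_iter = 50, half_size_mm = 25) {
  stopifnot(inherits(grid, "source_grid"))
  nodes <- grid_nodes_norm(grid, half_size_mm)
  n <- grid$n
  px <- estimates$x_norm
  py <- estimates$y_norm
  if (length(px) < min_events * nrow(nodes)) {
    abort(sprintf("need at least %d events (%d nodes x %d), got %d.",
                  min_events * nrow(nodes), nrow(nodes), min_events,
                  length(px)))
  }
  xc <- marginal_seed(px, n)
  yc <- marginal_seed(py, n)
  # seed each node with the outer product of the marginal cluster centres;
  # node_i indexes x (ascending), node_j indexes y
  cx <- xc[nodes$node_i + 1L]
  cy <- yc[nodes$node_j + 1L]
  iter <- 0L
  converged <- FALSE
  assign <- rep(1L, length(px))
  for (iter in seq_len(max_iter)) {
    assign <- nearest_cell(px, py, cx, cy)
    f <- factor(assign, levels = seq_len(nrow(nodes)))
    nx <- as.vector(tapply(px, f, mean))
    ny <- as.vector(tapply(py, f, mean))
    keep <- !is.na(nx)    # empty cells keep their previous centroid
    move <- max(abs(c(nx[keep] - cx[keep], ny[keep] - cy[keep])))
    cx[keep] <- nx[keep]
    cy[keep] <- ny[keep]
    if (move < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("source localization did not converge in %d iterations; returning best estimate.",
                 max_iter))
  }
  counts <- tabulate(assign, nbins = nrow(nodes))
  if (any(counts < min_events)) {
    starved <- nodes[counts < min_events, ]
    abort(sprintf(
      "node(s) with fewer than %d events: %s", min_events,
      paste(sprintf("(%d,%d)", starved$node_i, starved$node_j), collapse = ", ")))
  }
  nodes$x <- cx
  nodes$y <- cy
  nodes$n_events <- counts
  new_calibration_map(nodes, grid, converged, iter)
}

#' Average several calibration maps into a reference map
#'
#' Node-wise arithmetic mean of the measured centroids of the input maps
#' (nominally three normally calibrated detectors), used as the shared
#' reference calibration map of the shift-map accelerated calibration.
#'
#' @param maps List of `calibration_map` objects on the same grid.
#' @return A `calibration_map` with averaged centroids and summed counts.
#' @export
average_calibration_maps <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(purrr::map_lgl(maps, inherits, "calibration_map")))
  if (length(maps) != 3) {
    warn(sprintf("averaging %d calibration maps (3 are typical).",
                 length(maps)))
  }
  ref <- maps[[1]]$nodes
  for (m in maps[-1]) {
    if (!identical(m$nodes$node_i, ref$node_i) ||
        !identical(m$nodes$node_j, ref$node_j)) {
      abort("calibration maps use different grid indexing.")
    }
  }
  nodes <- ref
  col_of <- function(f) matrix(unlist(purrr::map(maps, f)), nrow = nrow(ref))
  nodes$x <- rowMeans(col_of(function(m) m$nodes$x))
  nodes$y <- rowMeans(col_of(function(m) m$nodes$y))
  nodes$n_events <- as.integer(rowSums(col_of(function(m) m$nodes$n_events)))
  new_calibration_map(nodes, maps[[1]]$grid,
                      all(purrr::map_lgl(maps, function(m) isTRUE(m$converged))),
                      NA)
}

#' @rdname localize_sources
#' @param object A `calibration_map`.
#' @export
autoplot.calibration_map <- function(object, ...) {
  nodes <- object$nodes
  ggplot2::ggplot(nodes) +
    ggplot2::geom_point(ggplot2::aes(.data$mech_x, .data$mech_y),
                        shape = 3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(.data$x, .data$y), colour = "red3",
                        size = 1) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "x (normalized)", y = "y (normalized)",
                  title = "Measured centroids (red) vs mechanical nodes (+)")
}
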