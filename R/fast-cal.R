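# Accelerated system calibrations.
#
# TEST1: the five LUTs of one normally calibrated donor detector are shared
# verbatim by every module.
#
# TEST2: three donors are normally calibrated and their calibration maps
# averaged into a reference map.  Every other module only needs a uniform
# irradiation: the bright edge ridge of its uniformity flood map is
# line-fitted, the four corner intersections are compared with the
# reference corners, the four corner shifts are interpolated into a smooth
# shift map, and the reference map is displaced accordingly to become that
# module's calibration map.  Energy and DOI factors come from the module's
# own uniformity events.

#' Share one detector's lookup tables across a bank (TEST1)
#'
#' @param reference_luts The donor detector's `lut_set`.
#' @param detector_ids Character vector of receiving detector ids.
#' @return Named list of `lut_set` copies, metadata recording the donor.
#' @export
test1_calibrate <- function(reference_luts, detector_ids) {
  stopifnot(inherits(reference_luts, "lut_set"))
  out <- purrr::map(detector_ids, function(id) {
    l <- reference_luts
    l$detector_id <- id
    l$provenance <- sprintf("test1 (shared from %s)",
                            reference_luts$detector_id)
    l
  })
  names(out) <- detector_ids
  out
}

# ---- corner detection ------------------------------------------------------

robust_line <- function(u, v) {
  # least-squares fit v ~ u with one 2-sigma outlier rejection pass
  fit <- stats::lm(v ~ u)
  r <- stats::residuals(fit)
  keep <- abs(r) <= 2 * sd(r)
  if (sum(keep) >= 3 && any(!keep)) fit <- stats::lm(v[keep] ~ u[keep])
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# Outermost crossing of `level` along one histogram lane, linearly
# interpolated between bins.  `from_low = TRUE` scans the low-coordinate
# flank (left/bottom edges).
lane_crossing <- function(counts1d, pos, level, from_low) {
  above <- which(counts1d >= level)
  if (length(above) < 3) return(NA_real_)
  if (from_low) {
    i <- above[1]
    if (i == 1) return(pos[1])
    pos[i - 1] + (level - counts1d[i - 1]) * (pos[i] - pos[i - 1]) /
      (counts1d[i] - counts1d[i - 1])
  } else {
    i <- above[length(above)]
    if (i == length(pos)) return(pos[length(pos)])
    pos[i + 1] + (level - counts1d[i + 1]) * (pos[i] - pos[i + 1]) /
      (counts1d[i] - counts1d[i + 1])
  }
}

# Extract the event-accumulation boundary of one side of a uniformity
# histogram and fit a line.  Lane by lane (rows for the left/right sides,
# columns for top/bottom), the boundary point is the outermost crossing of
# `level_frac` times the lane's interior plateau level (median of its
# occupied bins): outside the crystal the counts vanish, on the bright
# edge accumulation they peak, so the crossing tracks the effective active
# boundary.  Returns list(side, axis, intercept, slope): for left/right
# the line is x = intercept + slope * y; for top/bottom y = intercept +
# slope * x.
fit_edge_line <- function(h, side, margin = 0.1, min_cover = 0.3,
                          level_frac = 0.4) {
  counts <- h$counts
  xs <- h$x_centers
  ys <- h$y_centers
  along_x <- side %in% c("left", "right")
  lanes <- if (along_x) seq_along(ys) else seq_along(xs)
  lane_pos <- if (along_x) ys else xs
  pts <- vapply(lanes, function(r) {
    lane <- if (along_x) counts[, r] else counts[r, ]
    occ <- lane > 0
    if (sum(occ) < 5) return(NA_real_)
    level <- level_frac * median(lane[occ])
    lane_crossing(lane, if (along_x) xs else ys, level,
                  from_low = side %in% c("left", "bottom"))
  }, numeric(1))
  # drop the outer margin of lanes (edge curvature near the corners)
  occ_rng <- range(lane_pos[!is.na(pts)])
  good <- !is.na(pts) &
    lane_pos >= occ_rng[1] + margin * diff(occ_rng) &
    lane_pos <= occ_rng[2] - margin * diff(occ_rng)
  if (mean(!is.na(pts)) < min_cover || sum(good) < 10) {
    abort(sprintf("edge boundary on the %s side covers < %.0f%% of the side.",
                  side, 100 * min_cover))
  }
  ln <- robust_line(lane_pos[good], pts[good])
  list(side = side, axis = if (along_x) "x_of_y" else "y_of_x",
       intercept = ln[["intercept"]], slope = ln[["slope"]])
}

intersect_lines <- function(vert, horiz) {
  # vert: x = c1 + m1 y ; horiz: y = c2 + m2 x
  y <- (horiz$intercept + horiz$slope * vert$intercept) /
    (1 - horiz$slope * vert$slope)
  x <- vert$intercept + vert$slope * y
  c(x = x, y = y)
}

#' Detect the active-area corners of a uniformity flood map
#'
#' Uniform irradiation of a monolithic crystal piles events up along the
#' edges of the flood map (light truncation).  For each side, the outer
#' boundary of that accumulation — the outermost crossing of a fixed
#' fraction of the interior plateau level, lane by lane — is extracted and
#' fitted with a robust line; intersecting adjacent lines gives the four
#' corners of the effective active area.  The boundary (rather than the
#' accumulation ridge maximum) is used because it responds to
#' crystal-to-sensor misalignment like the calibration-map nodes do,
#' which is what the shift-map correction relies on.
#'
#' @param flood A `flood_hist` (from [flood_histogram()]) or an estimates
#'   table with `x_norm`, `y_norm` (histogrammed at `bins`).
#' @param bins Histogram bins per axis when `flood` is an event table.
#' @param margin Fraction of each side's extent excluded near the corners
#'   when fitting the edge lines (edge curvature).
#' @param level_frac Crossing level as a fraction of the lane's interior
#'   plateau.
#' @return A `corner_set`: tibble with corners TL, TR, BL, BR (`x`, `y`),
#'   carrying the four fitted edge lines as attribute `lines`.
#' @export
detect_corners <- function(flood, bins = 96, margin = 0.1,
                           level_frac = 0.4) {
  h <- if (inherits(flood, "flood_hist")) flood else flood_histogram(flood, bins)
  lines <- purrr::map(setNames(nm = c("left", "right", "top", "bottom")),
                      function(s) fit_edge_line(h, s, margin,
                                                level_frac = level_frac))
  corners <- tibble::tibble(
    corner = c("TL", "TR", "BL", "BR"),
    x = NA_real_, y = NA_real_)
  corners[1, c("x", "y")] <- as.list(intersect_lines(lines$left, lines$top))
  corners[2, c("x", "y")] <- as.list(intersect_lines(lines$right, lines$top))
  corners[3, c("x", "y")] <- as.list(intersect_lines(lines$left, lines$bottom))
  corners[4, c("x", "y")] <- as.list(intersect_lines(lines$right, lines$bottom))
  structure(corners, class = c("corner_set", class(corners)), lines = lines)
}

#' Average several corner sets corner-wise
#'
#' The reference corners of the shift-map calibration are the corner-wise
#' mean of the donors' individually detected corner sets.  (Detecting
#' corners on an averaged histogram instead would smear the edge
#' accumulations of misaligned donors into a wider rim and bias the
#' boundary outward.)
#'
#' @param corner_sets List of `corner_set` tables.
#' @return A `corner_set` with averaged coordinates.
#' @export
average_corner_sets <- function(corner_sets) {
  stopifnot(length(corner_sets) >= 1)
  base <- corner_sets[[1]]
  base$x <- rowMeans(vapply(corner_sets, function(co) co$x,
                            numeric(nrow(base))))
  base$y <- rowMeans(vapply(corner_sets, function(co) co$y,
                            numeric(nrow(base))))
  base
}

#' Shift of detected corners relative to reference corners
#'
#' `shift_k = reference_corner_k - detected_corner_k`, matched by corner
#' label: the displacement that carries each detected corner onto its
#' reference counterpart.
#'
#' @param corners,reference_corners `corner_set` tables (TL, TR, BL, BR).
#' @return Tibble with `corner`, `dx`, `dy`.
#' @export
corner_shifts <- function(corners, reference_corners) {
  stopifnot(identical(corners$corner, reference_corners$corner))
  tibble::tibble(
    corner = corners$corner,
    dx = reference_corners$x - corners$x,
    dy = reference_corners$y - corners$y)
}

# ---- shift-map interpolation ----------------------------------------------

# Bilinear value over the quadrilateral (BL, BR, TL, TR) at parameters
# (s, t) in [0,1]^2: F(s,t) = (1-s)(1-t) BL + s(1-t) BR + (1-s)t TL + st TR.
bilinear_eval <- function(s, t, vBL, vBR, vTL, vTR) {
  (1 - s) * (1 - t) * vBL + s * (1 - t) * vBR +
    (1 - s) * t * vTL + s * t * vTR
}

# Vectorized Newton inversion of the bilinear map for points inside the
# quadrilateral.
inverse_bilinear <- function(px, py, q) {
  s <- rep(0.5, length(px)); t <- rep(0.5, length(px))
  for (i in 1:25) {
    fx <- bilinear_eval(s, t, q$BL[1], q$BR[1], q$TL[1], q$TR[1]) - px
    fy <- bilinear_eval(s, t, q$BL[2], q$BR[2], q$TL[2], q$TR[2]) - py
    dxs <- (1 - t) * (q$BR[1] - q$BL[1]) + t * (q$TR[1] - q$TL[1])
    dxt <- (1 - s) * (q$TL[1] - q$BL[1]) + s * (q$TR[1] - q$BR[1])
    dys <- (1 - t) * (q$BR[2] - q$BL[2]) + t * (q$TR[2] - q$TL[2])
    dyt <- (1 - s) * (q$TL[2] - q$BL[2]) + s * (q$TR[2] - q$BR[2])
    det <- dxs * dyt - dxt * dys
    det[abs(det) < 1e-12] <- 1e-12
    s <- s - (fx * dyt - fy * dxt) / det
    t <- t - (fy * dxs - fx * dys) / det
  }
  list(s = s, t = t)
}

quad_from_corners <- function(corners) {
  get <- function(lbl) {
    r <- corners[corners$corner == lbl, ]
    c(r$x, r$y)
  }
  q <- list(TL = get("TL"), TR = get("TR"), BL = get("BL"), BR = get("BR"))
  e1 <- q$BR - q$BL; e2 <- q$TR - q$BR; e3 <- q$TL - q$TR; e4 <- q$BL - q$TL
  cross <- function(a, b) a[1] * b[2] - a[2] * b[1]
  sgn <- c(cross(e1, e2), cross(e2, e3), cross(e3, e4), cross(e4, e1))
  if (any(sgn == 0) || length(unique(sign(sgn))) != 1) {
    abort("corner quadrilateral is degenerate or non-convex.")
  }
  q
}

# Evaluate the four-generator shift interpolant at arbitrary points.
# Inside the corner quadrilateral: inverse-bilinear (generalized
# barycentric) interpolation, the natural-neighbour interpolant for four
# generators on a convex quadrilateral.  Outside: the value at the nearest
# point of the quadrilateral boundary (continuous extension).
eval_shift_field <- function(px, py, corners, shifts) {
  q <- quad_from_corners(corners)
  sh <- function(lbl, comp) shifts[[comp]][shifts$corner == lbl]
  st <- inverse_bilinear(px, py, q)
  s <- st$s; t <- st$t
  inside <- s >= 0 & s <= 1 & t >= 0 & t <= 1 & is.finite(s) & is.finite(t)
  dx <- bilinear_eval(pmin(pmax(s, 0), 1), pmin(pmax(t, 0), 1),
                      sh("BL", "dx"), sh("BR", "dx"),
                      sh("TL", "dx"), sh("TR", "dx"))
  dy <- bilinear_eval(pmin(pmax(s, 0), 1), pmin(pmax(t, 0), 1),
                      sh("BL", "dy"), sh("BR", "dy"),
                      sh("TL", "dy"), sh("TR", "dy"))
  out <- !inside
  if (any(out)) {
    # project outside points onto the nearest boundary segment and lerp the
    # two corner shifts of that segment
    edges <- list(
      list(a = q$BL, b = q$BR, la = "BL", lb = "BR"),
      list(a = q$BR, b = q$TR, la = "BR", lb = "TR"),
      list(a = q$TR, b = q$TL, la = "TR", lb = "TL"),
      list(a = q$TL, b = q$BL, la = "TL", lb = "BL"))
    ox <- px[out]; oy <- py[out]
    bestd <- rep(Inf, length(ox))
    bdx <- numeric(length(ox)); bdy <- numeric(length(ox))
    for (e in edges) {
      ab <- e$b - e$a
      tt <- pmin(pmax(((ox - e$a[1]) * ab[1] + (oy - e$a[2]) * ab[2]) /
                        sum(ab^2), 0), 1)
      qx <- e$a[1] + tt * ab[1]; qy <- e$a[2] + tt * ab[2]
      d <- (ox - qx)^2 + (oy - qy)^2
      upd <- d < bestd
      bestd[upd] <- d[upd]
      bdx[upd] <- (1 - tt[upd]) * sh(e$la, "dx") + tt[upd] * sh(e$lb, "dx")
      bdy[upd] <- (1 - tt[upd]) * sh(e$la, "dy") + tt[upd] * sh(e$lb, "dy")
    }
    dx[out] <- bdx
    dy[out] <- bdy
  }
  tibble::tibble(dx = dx, dy = dy)
}

#' Interpolate four corner shifts into a full-surface shift map
#'
#' Natural-neighbour interpolation of the four corner shift vectors over
#' the flood-map square.  With exactly four generators on a convex
#' quadrilateral this is the inverse-bilinear (generalized barycentric)
#' interpolant; outside the quadrilateral the value of the nearest boundary
#' point is used, so the map is continuous everywhere and exact at each
#' corner.
#'
#' @param corners A `corner_set` (the detector's detected corners).
#' @param shifts Corner shifts from [corner_shifts()].
#' @param grid_n Pixels per side of the rasterized map.
#' @return A `shift_map`: list with `dx`, `dy` matrices on the LUT pixel
#'   grid, the generating corners and shifts, and an evaluator
#'   `$at(x, y)`.
#' @export
interpolate_shift_map <- function(corners, shifts, grid_n = 500) {
  ctr <- lut_pixel_centers(grid_n)
  px <- rep(ctr, times = grid_n)
  py <- rep(ctr, each = grid_n)
  f <- eval_shift_field(px, py, corners, shifts)
  structure(list(
    dx = matrix(f$dx, grid_n, grid_n),
    dy = matrix(f$dy, grid_n, grid_n),
    grid_n = as.integer(grid_n),
    pixel_centers = ctr,
    corners = corners,
    shifts = shifts,
    at = function(x, y) eval_shift_field(x, y, corners, shifts)
  ), class = "shift_map")
}

#' @export
print.shift_map <- function(x, ...) {
  cat(sprintf("<shift_map %d x %d, |shift| up to %.4f>\n", x$grid_n,
              x$grid_n, max(abs(c(x$shifts$dx, x$shifts$dy)))))
  invisible(x)
}

#' Uniformity-map accelerated calibration of a detector bank (TEST2)
#'
#' Calibrates every detector from its uniformity acquisition alone, given a
#' reference calibration map (nominally the average of three normally
#' calibrated donors) and the reference corners: per detector, detect the
#' uniformity-map corners, compute the four corner shifts against the
#' reference, interpolate the shift map, displace the reference nodes into
#' the detector's frame (the negated shift field carries reference
#' features onto the detector), recompute the planar factors against the
#' mechanical positions, and fit the energy and DOI factors from the
#' detector's own uniformity events.
#'
#' @param reference_map Reference `calibration_map`
#'   (see [average_calibration_maps()]).
#' @param reference_corners Reference `corner_set` (nominally from the
#'   averaged donor uniformity histograms).
#' @param uniformity Named list (by detector id) of uniformity event
#'   estimates, or a single tibble with a `detector_id` column.
#' @param reference_factors Optional `voronoi_factors` used for cells with
#'   too few uniformity events.
#' @param grid_n LUT pixels per side.
#' @param min_events Minimum uniformity events per cell for energy/DOI fits.
#' @param stat_radius Passed to [voronoi_factors()].
#' @param bins Uniformity histogram bins for corner detection.
#' @param make_luts Rasterize LUTs per detector.
#' @return List with `$luts` (named list of `lut_set`), `$factors` (named
#'   list of `voronoi_factors`), `$maps` (shifted calibration maps),
#'   `$report` (per-detector tibble: corners, shifts, fallback counts,
#'   errors).  Detectors whose corner detection fails are reported and
#'   skipped.
#' @export
test2_calibrate <- function(reference_map, reference_corners, uniformity,
                            reference_factors = NULL, grid_n = 500,
                            min_events = 30, bins = 96, make_luts = TRUE,
                            stat_radius = c(Inf, 0.08)) {
  stopifnot(inherits(reference_map, "calibration_map"))
  if (is.data.frame(uniformity)) {
    uniformity <- split(uniformity, uniformity$detector_id)
  }
  ids <- names(uniformity)
  luts <- list(); factors <- list(); maps <- list()
  report <- purrr::map_dfr(ids, function(id) {
    est <- uniformity[[id]]
    res <- tryCatch({
      corners <- detect_corners(est, bins = bins)
      shifts <- corner_shifts(corners, reference_corners)
      nodes <- reference_map$nodes
      sh <- eval_shift_field(nodes$x, nodes$y, corners, shifts)
      # negate: shifts carry detector -> reference; nodes go the other way
      nodes$x <- nodes$x - sh$dx
      nodes$y <- nodes$y - sh$dy
      shifted <- new_calibration_map(nodes, reference_map$grid)
      fac <- voronoi_factors(est, shifted, min_events = min_events,
                             fallback = reference_factors,
                             stat_radius = stat_radius)
      maps[[id]] <<- shifted
      factors[[id]] <<- fac
      if (make_luts) {
        l <- rasterize_luts(fac, shifted, grid_n, id)
        l$provenance <- "test2 (shifted reference map)"
        luts[[id]] <<- l
      }
      tibble::tibble(
        detector_id = id, ok = TRUE, error = NA_character_,
        n_events = nrow(est),
        mean_shift_dx = mean(shifts$dx), mean_shift_dy = mean(shifts$dy),
        max_abs_shift = max(abs(c(shifts$dx, shifts$dy))),
        n_fallback = attr(fac, "n_fallback") %||% 0L)
    }, error = function(e) {
      tibble::tibble(detector_id = id, ok = FALSE,
                     error = conditionMessage(e), n_events = nrow(est),
                     mean_shift_dx = NA_real_, mean_shift_dy = NA_real_,
                     max_abs_shift = NA_real_, n_fallback = NA_integer_)
    })
    res
  })
  if (any(!report$ok)) {
    warn(sprintf("TEST2 failed for %d detector(s): %s",
                 sum(!report$ok),
                 paste(report$detector_id[!report$ok], collapse = ", ")))
  }
  list(luts = luts, factors = factors, maps = maps, report = report)
}
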