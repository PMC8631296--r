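# Voronoi partition of the flood map and the five per-cell factors.

#' Voronoi partition generated by a calibration map
#'
#' The 121 measured centroids generate a Voronoi tessellation of the
#' normalized flood-map square `[-1, 1]^2`: every point belongs to the cell
#' of its nearest centroid (Euclidean metric, ties to the lowest cell
#' index).  Cells are indexed 1..121 in the node order of the calibration
#' map.
#'
#' @param calmap A `calibration_map` (or a data frame with `x`, `y`).
#' @return A `voronoi_partition`: list with the centroid coordinates and a
#'   vectorized membership function `$cell(x, y)`.
#' @export
build_voronoi <- function(calmap) {
  nodes <- if (inherits(calmap, "calibration_map")) calmap$nodes else
    tibble::as_tibble(calmap)
  cx <- nodes$x
  cy <- nodes$y
  if (anyDuplicated(cbind(cx, cy))) {
    abort("duplicate centroids: Voronoi partition is not defined.")
  }
  structure(list(
    centroids = tibble::tibble(cell = seq_along(cx), x = cx, y = cy),
    n_cells = length(cx),
    cell = function(x, y) nearest_cell(x, y, cx, cy)
  ), class = "voronoi_partition")
}

#' @export
print.voronoi_partition <- function(x, ...) {
  cat(sprintf("<voronoi_partition, %d cells on [-1,1]^2>\n", x$n_cells))
  invisible(x)
}

#' Planar Voronoi factors: deviation of measured from mechanical positions
#'
#' For every cell, the planar correction factors are the additive deviation
#' of the measured source centroid from its mechanical position in
#' normalized units: `f_x = mech_x - x`, `f_y = mech_y - y`.  Calibration
#' adds the factor of the event's cell, so applying the factors to the
#' centroids themselves reproduces the mechanical positions exactly.
#'
#' @param calmap A `calibration_map`.
#' @return Tibble with `cell`, `node_i`, `node_j`, `f_x`, `f_y`.
#' @export
compute_xy_factors <- function(calmap) {
  nodes <- calmap$nodes
  tibble::tibble(
    cell = seq_len(nrow(nodes)),
    node_i = nodes$node_i, node_j = nodes$node_j,
    f_x = nodes$mech_x - nodes$x,
    f_y = nodes$mech_y - nodes$y)
}

# Photopeak channel of an energy sample: mode of a 256-bin histogram, then
# a Gaussian fit restricted to +/- 1.5 FWHM around the mode; falls back to
# the mode (with a warning) if the fit fails.
find_photopeak <- function(e, bins = 256) {
  e <- e[is.finite(e) & e > 0]
  if (length(e) < 10) abort("too few events for a photopeak estimate.")
  # clip stray outliers so the binning does not depend on sample extremes,
  # and keep bins populated for small samples
  rng <- quantile(e, c(0.001, 0.999), names = FALSE)
  e <- e[e >= rng[1] & e <= rng[2]]
  bins <- min(bins, max(32, floor(length(e) / 10)))
  h <- graphics::hist(e, breaks = seq(min(e), max(e), length.out = bins + 1),
                      plot = FALSE)
  mode_i <- which.max(h$counts)
  mode_x <- h$mids[mode_i]
  half <- h$counts[mode_i] / 2
  above <- h$counts >= half
  # contiguous above-half run containing the mode -> FWHM estimate
  lo <- mode_i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- mode_i; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  fwhm <- max(h$mids[hi] - h$mids[lo], diff(h$mids[1:2]))
  win <- abs(h$mids - mode_x) <= 1.5 * fwhm
  df <- data.frame(x = h$mids[win], n = h$counts[win])
  fit <- tryCatch(
    nls(n ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
        start = list(a = h$counts[mode_i], mu = mode_x, s = fwhm / 2.355)),
    error = function(e) NULL)
  mu <- if (is.null(fit)) NA_real_ else coef(fit)[["mu"]]
  # reject fits that wander out of the fit window
  if (!is.finite(mu) || abs(mu - mode_x) > 1.5 * fwhm) {
    warn("photopeak Gaussian fit failed; using histogram mode.")
    return(mode_x)
  }
  mu
}

#' Per-cell energy Voronoi factors (photopeak channels)
#'
#' The energy factor of a cell is the photopeak position (in ADC channels)
#' of the cell's energy histogram.  The corrected energy of an event is
#' `E * f_E(central cell) / f_E(cell)`, so the central cell is the
#' reference and its correction ratio is 1 by construction.
#'
#' @param estimates Event estimates carrying `E_channels` and a `cell`
#'   column (Voronoi membership).
#' @param n_cells Total number of cells.
#' @param min_events Cells with fewer events get `NA` (resolved by the
#'   caller, e.g. with a reference factor).
#' @return Numeric vector of length `n_cells` with the per-cell photopeak.
#' @export
compute_energy_factors <- function(estimates, n_cells, min_events = 30) {
  split_e <- split(estimates$E_channels,
                   factor(estimates$cell, levels = seq_len(n_cells)))
  unname(vapply(split_e, function(e) {
    if (length(e) < min_events) return(NA_real_)
    find_photopeak(e)
  }, numeric(1)))
}

#' Fit the limits and edge width of an E/Imax histogram
#'
#' Models the raw DOI statistic of a cell as a sharply bounded
#' distribution on `[a, b]` with error-function-smoothed edges of shared
#' width `sigma_int`.  Because the interaction depth follows an
#' attenuation exponential and the DOI mapping is close to affine, the
#' interior density is modelled as an exponential tilt `exp(k t)` between
#' the edges; the convolution with the Gaussian edge smear has the closed
#' form fitted here by least squares on a binned histogram (the flat box
#' is the `k = 0` special case).  The two DOI Voronoi factors are
#' `a - sigma_int` and `b + sigma_int`, the ratio values later anchored to
#' the physical crystal thickness.
#'
#' @param doi_raw Numeric vector of raw `E/Imax` values of one cell.
#' @param bins Maximum histogram bins used for the fit (reduced for small
#'   samples).
#' @return A `doi_fit`: list with `a`, `b`, `sigma_int`, `tilt`, `f_doi1`,
#'   `f_doi2` and the histogram used.
#' @export
#' @examples
#' x <- runif(5000, 2, 6) + rnorm(5000, 0, 0.1)
#' fit_doi_limits(x)[c("a", "b", "sigma_int")]
fit_doi_limits <- function(doi_raw, bins = 48) {
  x <- doi_raw[is.finite(doi_raw)]
  if (length(x) < 20) abort("too few events for a DOI-limit fit.")
  rng <- range(x)
  if (diff(rng) <= 0) abort("degenerate E/Imax histogram (single value).")
  n <- length(x)
  bins <- min(bins, max(24, floor(n / 6)))
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  if (sum(h$counts > 0) < 2) abort("degenerate E/Imax histogram (single bin).")
  mids <- h$mids
  bw <- diff(brk[1:2])
  a0 <- quantile(x, 0.03, names = FALSE)
  b0 <- quantile(x, 0.97, names = FALSE)
  w <- max(b0 - a0, 4 * bw)
  dens <- function(t, a, b, s, k) {
    edge <- pnorm((t - a - k * s^2) / s) - pnorm((t - b - k * s^2) / s)
    if (abs(k) < 1e-8) {
      (pnorm((t - a) / s) - pnorm((t - b) / s)) / (b - a)
    } else {
      k / (exp(k * (b - a)) - 1) * exp(k * (t - a) + k^2 * s^2 / 2) * edge
    }
  }
  # bounded reparameterization keeps the edges near their quantile seeds
  # and the width/tilt in sane ranges
  unpack <- function(p) list(
    a = a0 + w / 4 * tanh(p[1]),
    b = b0 + w / 4 * tanh(p[2]),
    s = bw / 4 + w / 4 * stats::plogis(p[3]),
    k = 8 / w * tanh(p[4]))
  obj <- function(p) {
    q <- unpack(p)
    sum((h$counts - n * bw * dens(mids, q$a, q$b, q$s, q$k))^2)
  }
  fit <- optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-10))
  q <- unpack(fit$par)
  structure(list(a = q$a, b = q$b, sigma_int = q$s, tilt = q$k,
                 f_doi1 = q$a - q$s, f_doi2 = q$b + q$s,
                 histogram = tibble::tibble(mid = mids, count = h$counts)),
            class = "doi_fit")
}

#' @export
print.doi_fit <- function(x, ...) {
  cat(sprintf("<doi_fit a=%.3f b=%.3f sigma=%.3f -> factors [%.3f, %.3f]>\n",
              x$a, x$b, x$sigma_int, x$f_doi1, x$f_doi2))
  invisible(x)
}

#' Calibrate the raw E/Imax statistic into millimetres
#'
#' Affine map anchoring the two DOI factors of a cell to the physical
#' crystal span: `f_doi1` maps to 0 mm and `f_doi2` to `thickness_mm`
#' (15 mm), with the result clipped to the crystal.  In the package's light
#' model `E/Imax` decreases towards the photosensor plane, so the
#' calibrated coordinate runs from the sensor face (0 mm) to the entrance
#' face (15 mm).
#'
#' @param doi_raw Raw `E/Imax` values.
#' @param f_doi1,f_doi2 Lower/upper DOI factors of the events' cells
#'   (scalars or vectors matching `doi_raw`).
#' @param thickness_mm Crystal thickness (mm).
#' @return Calibrated DOI in mm, in `[0, thickness_mm]`.
#' @export
#' @examples
#' calibrate_doi(c(1.5, 3, 4.5), 1.5, 4.5)
calibrate_doi <- function(doi_raw, f_doi1, f_doi2, thickness_mm = 15) {
  if (any(f_doi2 <= f_doi1)) abort("requires f_doi1 < f_doi2.")
  pmin(pmax(thickness_mm * (doi_raw - f_doi1) / (f_doi2 - f_doi1), 0),
       thickness_mm)
}

#' Assemble the five Voronoi factors of one detector
#'
#' Computes, for every Voronoi cell of the calibration map: the planar
#' deviation factors, the energy photopeak factor, and the two DOI limit
#' factors fitted from the cell's E/Imax histogram.
#'
#' @param estimates Event estimates of the calibration (or uniformity)
#'   acquisition used for the energy and DOI statistics.
#' @param calmap The detector's `calibration_map` (defines the partition
#'   and the planar factors).
#' @param min_events Minimum events per cell for the energy/DOI fits;
#'   starved cells fall back to `fallback` or to a whole-detector fit.
#' @param fallback Optional `voronoi_factors` supplying `f_e`, `f_doi1`,
#'   `f_doi2` for starved cells (used by the accelerated calibration).
#' @param stat_radius Normalized radii around each cell centroid from
#'   which the energy and DOI statistics are taken: length-2 vector
#'   `(energy, doi)`, default `c(Inf, 0.08)` (2 mm on a 50 mm crystal for
#'   the DOI footprint), or a scalar used for both.  Restricting the DOI
#'   statistics to a common footprint makes the fitted E/Imax limits
#'   comparable between collimated-array and uniform acquisitions, whose
#'   within-cell spatial sampling otherwise differs; the photopeak is
#'   spatially smooth and prefers the full cell statistics.  Cells with
#'   fewer than `min_events` inside a radius fall back to all their
#'   events; `Inf` disables the restriction.
#' @return A `voronoi_factors` tibble: `cell`, `node_i`, `node_j`, `f_x`,
#'   `f_y`, `f_e`, `doi_a`, `doi_b`, `doi_sigma`, `f_doi1`, `f_doi2`, plus
#'   attributes `central_cell` and `n_fallback`.
#' @export
voronoi_factors <- function(estimates, calmap, min_events = 30,
                            fallback = NULL, stat_radius = c(Inf, 0.08)) {
  if (length(stat_radius) == 1) stat_radius <- rep(stat_radius, 2)
  part <- build_voronoi(calmap)
  est <- dplyr::mutate(estimates,
                       cell = part$cell(.data$x_norm, .data$y_norm))
  fac <- compute_xy_factors(calmap)
  n_cells <- nrow(fac)
  # per cell: prefer the centroid-footprint events, keep all if starved
  restrict <- function(est, radius) {
    if (!is.finite(radius)) return(est)
    cx <- calmap$nodes$x[est$cell]
    cy <- calmap$nodes$y[est$cell]
    near <- (est$x_norm - cx)^2 + (est$y_norm - cy)^2 <= radius^2
    n_near <- tabulate(est$cell[near], nbins = n_cells)
    est[near | n_near[est$cell] < min_events, ]
  }
  est_e <- restrict(est, stat_radius[1])
  fac$f_e <- compute_energy_factors(est_e, n_cells, min_events)

  est_d <- restrict(est, stat_radius[2])
  doi_split <- split(est_d$doi_raw, factor(est_d$cell, levels = seq_len(n_cells)))
  fits <- purrr::map(doi_split, function(d) {
    if (length(d) < min_events) return(NULL)
    tryCatch(fit_doi_limits(d), error = function(e) NULL)
  })
  fac$doi_a <- unname(purrr::map_dbl(fits, function(f) f$a %||% NA_real_))
  fac$doi_b <- unname(purrr::map_dbl(fits, function(f) f$b %||% NA_real_))
  fac$doi_sigma <- unname(purrr::map_dbl(fits, function(f) f$sigma_int %||% NA_real_))
  fac$f_doi1 <- fac$doi_a - fac$doi_sigma
  fac$f_doi2 <- fac$doi_b + fac$doi_sigma

  missing <- !complete.cases(fac[c("f_e", "f_doi1", "f_doi2")])
  n_fb <- sum(missing)
  if (n_fb > 0) {
    if (!is.null(fallback)) {
      warn(sprintf("%d cell(s) below %d events; using reference factors.",
                   n_fb, min_events))
      for (col in c("f_e", "doi_a", "doi_b", "doi_sigma", "f_doi1", "f_doi2")) {
        fac[[col]][missing] <- fallback[[col]][missing]
      }
    } else {
      warn(sprintf("%d cell(s) below %d events; using whole-detector fits.",
                   n_fb, min_events))
      fac$f_e[missing & is.na(fac$f_e)] <- find_photopeak(est_e$E_channels)
      gfit <- fit_doi_limits(est_d$doi_raw)
      for (col in c("doi_a", "doi_b", "doi_sigma", "f_doi1", "f_doi2")) {
        nm <- c(doi_a = "a", doi_b = "b", doi_sigma = "sigma_int",
                f_doi1 = "f_doi1", f_doi2 = "f_doi2")[[col]]
        fac[[col]][missing & is.na(fac[[col]])] <- gfit[[nm]]
      }
    }
  }
  # central cell: the mechanical grid centre node
  ctr <- (calmap$grid$n - 1L) %/% 2L
  central <- which(fac$node_i == ctr & fac$node_j == ctr)
  structure(fac, class = c("voronoi_factors", class(fac)),
            central_cell = central, n_fallback = n_fb)
}
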