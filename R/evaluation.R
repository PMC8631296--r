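# Comparison metrics between calibrations and image-quality figures.

factors_of <- function(x) {
  if (inherits(x, "voronoi_calibration")) x$factors else x
}

#' Correlation factors between an accelerated and the Normal calibration
#'
#' For each Voronoi cell and each of the five quantities (X, Y, DOI1, DOI2,
#' Energy), the correlation factor is the ratio of the accelerated
#' ("test") factor value to the Normal one; a perfectly reproduced
#' calibration gives 1 everywhere.  Planar factors can legitimately be
#' near zero (central cells), where the ratio is unstable: cells with
#' `|normal factor| < eps` are excluded from the planar means and counted.
#'
#' @param test_factors,normal_factors `voronoi_factors` tables (or
#'   `voronoi_calibration` objects) on the same 121-cell indexing.
#' @param eps Exclusion threshold on the Normal planar factor magnitude.
#' @return A `cf_table`: tibble with `cell`, `quantity` (X, Y, DOI1, DOI2,
#'   Energy), `cf`, `excluded`.
#' @export
correlation_factors <- function(test_factors, normal_factors, eps = 1e-3) {
  tf <- factors_of(test_factors)
  nf <- factors_of(normal_factors)
  if (nrow(tf) != nrow(nf)) {
    abort(sprintf("cell count mismatch: %d vs %d.", nrow(tf), nrow(nf)))
  }
  cols <- c(X = "f_x", Y = "f_y", DOI1 = "f_doi1", DOI2 = "f_doi2",
            Energy = "f_e")
  out <- purrr::map_dfr(names(cols), function(q) {
    col <- cols[[q]]
    tibble::tibble(
      cell = tf$cell,
      quantity = q,
      cf = tf[[col]] / nf[[col]],
      excluded = q %in% c("X", "Y") & abs(nf[[col]]) < eps)
  })
  out$quantity <- factor(out$quantity, levels = names(cols))
  structure(out, class = c("cf_table", class(out)))
}

#' Summarize correlation factors per quantity
#'
#' Mean of the per-cell correlation factors (excluded cells dropped) for
#' each of the five quantities, the estimator used to judge how well an
#' accelerated calibration reproduces the Normal one.
#'
#' @param cf A `cf_table` from [correlation_factors()], or a data frame
#'   binding several (e.g. with a `detector_id` column), in which case the
#'   grouping columns are preserved.
#' @param ... Extra grouping columns (tidy-select), e.g. `detector_id`.
#' @return Tibble with `quantity`, `cf_mean`, `n_cells`, `n_excluded`.
#' @export
cf_summary <- function(cf, ...) {
  cf |>
    dplyr::group_by(..., .data$quantity) |>
    dplyr::summarise(
      cf_mean = mean(.data$cf[!.data$excluded]),
      n_cells = dplyr::n(),
      n_excluded = sum(.data$excluded),
      .groups = "drop")
}

#' FWHM of a position profile
#'
#' Histograms the sample, locates the maximum, and finds the half-maximum
#' crossings on both flanks by linear interpolation between neighbouring
#' bins.  If several separated peaks rise above half maximum the widest
#' span is returned with a warning.
#'
#' @param values Numeric sample (e.g. calibrated positions, mm).
#' @param bin_width Histogram bin width in the units of `values`.
#' @return FWHM in the units of `values`.
#' @export
#' @examples
#' profile_fwhm(rnorm(1e4), 0.25)   # ~ 2.355
profile_fwhm <- function(values, bin_width = 0.25) {
  values <- values[is.finite(values)]
  if (length(values) < 100) abort("need at least 100 values for a profile.")
  rng <- range(values)
  brk <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = brk, plot = FALSE)
  n <- h$counts
  mids <- h$mids
  peak <- which.max(n)
  half <- n[peak] / 2
  above <- n >= half
  runs <- rle(above)
  if (sum(runs$values) > 1) {
    warn("profile has multiple peaks above half maximum; returning the widest span.")
  }
  cross <- function(i, j) {
    # linear interpolation of the half-max crossing between bins i and j
    mids[i] + (half - n[i]) * (mids[j] - mids[i]) / (n[j] - n[i])
  }
  lo <- min(which(above))
  hi <- max(which(above))
  left <- if (lo == 1) mids[1] - bin_width / 2 else cross(lo - 1, lo)
  right <- if (hi == length(n)) mids[length(n)] + bin_width / 2 else cross(hi + 1, hi)
  right - left
}

as_voi_index <- function(voi, image) {
  if (is.logical(voi)) which(voi) else as.integer(voi)
}

#' Contrast-to-noise ratio of hot volumes of interest
#'
#' `CNR = (mean hot VOI - background level) / background SD`, with the
#' background level and standard deviation computed over the pooled voxels
#' of all background VOIs.
#'
#' @param image Numeric array (any dimensionality) of voxel values.
#' @param hot_vois List of hot VOIs (logical masks or voxel index vectors).
#' @param background_vois List of background VOIs (nominally 12).
#' @return Tibble with one row per hot VOI: `voi`, `hot_mean`, `cnr`, plus
#'   the shared `background_level` and `background_sd`.
#' @export
cnr <- function(image, hot_vois, background_vois) {
  bg_idx <- unlist(lapply(background_vois, as_voi_index, image))
  if (length(bg_idx) == 0) abort("background VOIs are empty.")
  hot_idx <- lapply(hot_vois, as_voi_index, image)
  if (any(lengths(hot_idx) == 0)) abort("hot VOIs must be non-empty.")
  if (any(unlist(hot_idx) %in% bg_idx)) {
    abort("hot and background VOIs must be disjoint.")
  }
  bg_level <- mean(image[bg_idx])
  bg_sd <- sd(image[bg_idx])
  if (bg_sd == 0) abort("background standard deviation is zero.")
  tibble::tibble(
    voi = seq_along(hot_vois),
    hot_mean = vapply(hot_idx, function(i) mean(image[i]), numeric(1)),
    background_level = bg_level,
    background_sd = bg_sd) |>
    dplyr::mutate(cnr = (.data$hot_mean - bg_level) / bg_sd)
}

#' Percent contrast of hot volumes of interest
#'
#' `Contrast(%) = 100 * (mean hot VOI - background level) / mean hot VOI`.
#'
#' @inheritParams cnr
#' @param background_level Scalar background level (e.g. from [cnr()]), or
#'   a list of background VOIs to pool.
#' @return Tibble with `voi`, `hot_mean`, `contrast_pct`.
#' @export
contrast <- function(image, hot_vois, background_level) {
  if (is.list(background_level)) {
    background_level <- mean(image[unlist(lapply(background_level,
                                                 as_voi_index, image))])
  }
  hot_idx <- lapply(hot_vois, as_voi_index, image)
  hot_mean <- vapply(hot_idx, function(i) mean(image[i]), numeric(1))
  if (any(hot_mean <= 0)) abort("hot VOI means must be positive.")
  tibble::tibble(
    voi = seq_along(hot_vois),
    hot_mean = hot_mean,
    contrast_pct = 100 * (hot_mean - background_level) / hot_mean)
}

#' Synthetic image-quality phantom
#'
#' Builds a voxelized cylinder phantom (1 mm voxels) with six hot rods of
#' decreasing diameter in a warm background, mirroring a capillary
#' image-quality phantom with a configurable rod-to-background activity
#' ratio, plus matching hot and background VOIs.  Marked `synthetic`: it
#' stands in for a reconstructed phantom image, which the package does not
#' produce.
#'
#' @param ratio Rod-to-background activity concentration ratio.
#' @param background Mean background voxel value.
#' @param rod_diameters_mm Diameters of the six rods.
#' @param outer_diameter_mm,height_mm Phantom envelope.
#' @param rod_height_mm Rod length; hot VOIs use a 25 mm central section.
#' @param poisson Add Poisson noise?
#' @return List with `image` (3-D array), `hot_vois` (6 index vectors),
#'   `background_vois` (12 index vectors).
#' @export
synthetic_iq_phantom <- function(ratio = 38, background = 10,
                                 rod_diameters_mm = c(20, 15, 12, 9, 6, 4.5),
                                 outer_diameter_mm = 135, height_mm = 60,
                                 rod_height_mm = 60, poisson = TRUE) {
  n_xy <- ceiling(outer_diameter_mm) + 2
  n_z <- ceiling(height_mm)
  cx <- (n_xy + 1) / 2
  xs <- seq_len(n_xy) - cx
  zc <- seq_len(n_z) - (n_z + 1) / 2
  r2 <- outer(xs^2, xs^2, "+")
  in_cyl <- r2 <= (outer_diameter_mm / 2)^2
  img <- array(0, c(n_xy, n_xy, n_z))
  lam <- array(0, c(n_xy, n_xy, n_z))
  lam[] <- background * as.vector(in_cyl)
  ring_r <- outer_diameter_mm / 2 - max(rod_diameters_mm) / 2 - 15
  ang <- (seq_along(rod_diameters_mm) - 1) * 2 * pi / length(rod_diameters_mm)
  rod_centers <- cbind(ring_r * cos(ang), ring_r * sin(ang))
  rod_masks <- vector("list", length(rod_diameters_mm))
  for (k in seq_along(rod_diameters_mm)) {
    d2 <- outer((xs - rod_centers[k, 1])^2, (xs - rod_centers[k, 2])^2, "+")
    plane <- d2 <= (rod_diameters_mm[k] / 2)^2
    zin <- abs(zc) <= rod_height_mm / 2
    mask <- array(FALSE, c(n_xy, n_xy, n_z))
    mask[, , zin] <- plane
    rod_masks[[k]] <- mask
    lam[mask] <- background * ratio
  }
  img[] <- if (poisson) rpois(length(lam), lam) else lam
  # hot VOIs: rod cross-section over a centred 25 mm height
  hot_vois <- lapply(rod_masks, function(mask) {
    m <- mask
    m[, , abs(zc) > 12.5] <- FALSE
    which(m)
  })
  # 12 background VOIs: 8 mm radius cylinders on an inner ring between rods
  bg_r <- ring_r * 0.45
  bg_ang <- (seq_len(12) - 0.5) * 2 * pi / 12
  background_vois <- lapply(seq_len(12), function(k) {
    c0 <- c(bg_r * cos(bg_ang[k]), bg_r * sin(bg_ang[k]))
    d2 <- outer((xs - c0[1])^2, (xs - c0[2])^2, "+")
    plane <- d2 <= 8^2
    m <- array(FALSE, c(n_xy, n_xy, n_z))
    m[, , abs(zc) <= 12.5] <- plane
    which(m)
  })
  list(image = img, hot_vois = hot_vois, background_vois = background_vois)
}
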