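# End-to-end comparison study on a simulated detector bank: calibrates
# every module Normally (ground truth), then with the shared-LUT (TEST1)
# and shift-map (TEST2) accelerations, and measures correlation factors
# and pooled point-source residual profiles for both.

#' Simulate and calibrate a detector bank three ways
#'
#' Builds a bank of detectors with inter-detector variability, runs the
#' full per-detector Voronoi calibration on each module (Normal), shares
#' the first module's LUT factors across the bank (TEST1), and runs the
#' uniformity shift-map calibration with the first `n_reference` modules
#' as donors (TEST2).  Correlation factors of both accelerations against
#' Normal are computed per non-donor detector, and point sources at three
#' radial positions are viewed by every non-donor module: the residuals
#' (calibrated minus true position), pooled over the ring, give the
#' per-method FWHM comparison — per-module calibration biases broaden the
#' pooled profile exactly as they blur a reconstructed source.
#'
#' @param n_detectors Modules in the bank.
#' @param seed Master seed; every stage derives an independent stream.
#' @param gain_sd,offset_sd_mm,reflectivity_sd Bank variability
#'   (see [make_detector_bank()]).
#' @param events_per_source Calibration-acquisition events per source node.
#' @param n_uniformity Uniformity events per detector.
#' @param n_reference Donor detectors for TEST2 (nominally 3).
#' @param grid_n LUT pixels per side for the probe-detector LUTs.
#' @param min_events Minimum events per node/cell.
#' @param base_cfg Base [detector_config()].
#' @param grid The [source_grid()] to acquire.
#' @return A `bank_study` list: `$cf` (per-detector, per-method, per-
#'   quantity CF summary), `$cf_cells` (all per-cell CF values), `$fwhm`
#'   (per-method ring-pooled point-source residual FWHM, mm),
#'   `$recovery_rms_mm` (Normal interior-node recovery of the probe
#'   detector), `$bank`, `$report`.
#' @export
bank_study <- function(n_detectors = 24, seed = 1,
                       gain_sd = 0.05, offset_sd_mm = 0.5,
                       reflectivity_sd = 0.02,
                       events_per_source = 300, n_uniformity = 150000,
                       n_reference = 3, grid_n = 150, min_events = 30,
                       base_cfg = detector_config(), grid = source_grid()) {
  stopifnot(n_detectors > n_reference)
  bank <- make_detector_bank(n_detectors, gain_sd, offset_sd_mm,
                             reflectivity_sd, base_cfg, seed)
  ids <- names(bank)

  # Normal calibration (ground truth) of every module; LUTs only for the
  # probe module (the last, never a donor), the rest need factors only.
  probe <- ids[n_detectors]
  normal <- purrr::imap(bank, function(cfg, id) {
    ev <- with_stage_seed(seed, "grid", id, expr =
      simulate_grid_acquisition(grid, events_per_source, cfg))
    normal_calibrate(estimate_events(ev), grid, grid_n = grid_n,
                     min_events = min_events, make_luts = FALSE,
                     detector_id = id)
  })

  # Uniformity acquisitions (all modules; donors feed the reference corners)
  uni <- purrr::imap(bank, function(cfg, id) {
    with_stage_seed(seed, "uniformity", id, expr =
      estimate_events(simulate_uniform_acquisition(n_uniformity, cfg)))
  })

  donors <- ids[seq_len(n_reference)]
  reference_map <- average_calibration_maps(
    purrr::map(normal[donors], "map"))
  reference_corners <- average_corner_sets(
    purrr::map(uni[donors], detect_corners))
  reference_factors <- average_reference_factors(
    purrr::map(normal[donors], "factors"))

  test2 <- test2_calibrate(reference_map, reference_corners,
                           uni[setdiff(ids, donors)],
                           reference_factors = reference_factors,
                           grid_n = grid_n, min_events = min_events,
                           make_luts = FALSE)

  # TEST1: donor is the first module; CF uses its factors directly
  t1_factors <- normal[[ids[1]]]$factors

  eval_ids <- setdiff(ids, donors)
  cf_cells <- purrr::map_dfr(eval_ids, function(id) {
    dplyr::bind_rows(
      dplyr::mutate(correlation_factors(t1_factors, normal[[id]]$factors),
                    method = "TEST1", detector_id = id),
      dplyr::mutate(correlation_factors(test2$factors[[id]],
                                        normal[[id]]$factors),
                    method = "TEST2", detector_id = id))
  })
  cf <- cf_summary(cf_cells, .data$method, .data$detector_id)

  # Ring-pooled point-source profiles: the same source position seen by
  # every non-donor module; per-module calibration biases broaden the
  # pooled profile, which is what distinguishes the methods at system
  # level.  LUTs are rasterized per module for each method.
  t1_luts <- test1_calibrate(
    rasterize_luts(t1_factors, normal[[ids[1]]]$map, grid_n, ids[1]),
    eval_ids)
  source_x <- c(0, 11.5, 18.4)
  pool <- function(luts_for) {
    unlist(purrr::map(eval_ids, function(id) {
      ev <- with_stage_seed(seed, "pointsource", id, expr = {
        truth <- tibble::tibble(
          x_mm = rep(source_x, each = 400) +
            runif(1200, -0.125, 0.125),
          y_mm = runif(1200, -0.5, 0.5),
          depth_mm = sample_depth(1200, bank[[id]]$attenuation_mm_inv,
                                  bank[[id]]$crystal_mm[3]),
          energy_keV = sample_energy(1200, bank[[id]]))
        estimate_events(simulate_events(truth, bank[[id]]))
      })
      cal <- calibrate_events(ev, luts_for(id))
      cal$x_cal_mm - cal$x_mm
    }))
  }
  normal_luts <- purrr::map(
    setNames(nm = eval_ids),
    function(id) rasterize_luts(normal[[id]]$factors, normal[[id]]$map,
                                grid_n, id))
  test2_luts <- purrr::map(
    setNames(nm = eval_ids),
    function(id) rasterize_luts(test2$factors[[id]], test2$maps[[id]],
                                grid_n, id))
  fwhm <- c(
    Normal = profile_fwhm(pool(function(id) normal_luts[[id]]), 0.1),
    TEST1 = profile_fwhm(pool(function(id) t1_luts[[id]]), 0.1),
    TEST2 = profile_fwhm(pool(function(id) test2_luts[[id]]), 0.1))

  # probe events for the recovery check
  probe_ev <- with_stage_seed(seed, "probe", probe, expr =
    estimate_events(simulate_grid_acquisition(grid, events_per_source,
                                              bank[[probe]])))
  # Normal parameter recovery on the probe module (interior nodes)
  cal_probe <- calibrate_events(probe_ev, normal_luts[[probe]])
  rec <- dplyr::tibble(node_i = probe_ev$node_i, node_j = probe_ev$node_j,
                       x = cal_probe$x_cal_mm, y = cal_probe$y_cal_mm) |>
    dplyr::group_by(.data$node_i, .data$node_j) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::left_join(grid$nodes, by = c("node_i", "node_j"))
  interior <- rec$node_i >= 1 & rec$node_i <= grid$n - 2 &
    rec$node_j >= 1 & rec$node_j <= grid$n - 2
  recovery_rms <- sqrt(mean((rec$x[interior] - rec$mech_x_mm[interior])^2 +
                              (rec$y[interior] - rec$mech_y_mm[interior])^2))

  structure(list(
    cf = cf, cf_cells = cf_cells, fwhm = fwhm,
    recovery_rms_mm = recovery_rms,
    bank = bank, report = test2$report,
    donors = donors, probe = probe, seed = seed
  ), class = "bank_study")
}

# Node-wise mean of donor factor tables (energy/DOI fallback reference).
average_reference_factors <- function(factor_list) {
  base <- factor_list[[1]]
  for (col in c("f_e", "doi_a", "doi_b", "doi_sigma", "f_doi1", "f_doi2")) {
    base[[col]] <- rowMeans(sapply(factor_list, function(f) f[[col]]))
  }
  base
}

#' @export
print.bank_study <- function(x, ...) {
  cat(sprintf("<bank_study: %d detectors, donors %s, probe %s>\n",
              length(x$bank), paste(x$donors, collapse = ","), x$probe))
  print(cf_summary(x$cf_cells, .data$method))
  cat(sprintf("FWHM (mm): %s\n",
              paste(sprintf("%s %.2f", names(x$fwhm), x$fwhm), collapse = ", ")))
  invisible(x)
}

#' @rdname bank_study
#' @param x A `bank_study`.
#' @param ... Unused.
#' @export
tidy.bank_study <- function(x, ...) x$cf

#' @rdname bank_study
#' @export
glance.bank_study <- function(x, ...) {
  dev <- x$cf_cells |>
    dplyr::filter(.data$quantity %in% c("X", "Y"), !.data$excluded) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_abs_cf_dev = mean(abs(.data$cf - 1)),
                     .groups = "drop")
  tibble::tibble(
    n_detectors = length(x$bank),
    mean_abs_cf_dev_xy_test1 = dev$mean_abs_cf_dev[dev$method == "TEST1"],
    mean_abs_cf_dev_xy_test2 = dev$mean_abs_cf_dev[dev$method == "TEST2"],
    fwhm_normal_mm = x$fwhm[["Normal"]],
    fwhm_test1_mm = x$fwhm[["TEST1"]],
    fwhm_test2_mm = x$fwhm[["TEST2"]],
    recovery_rms_mm = x$recovery_rms_mm)
}
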