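#' Build and validate a pipeline run configuration
#'
#' @param seed Master seed (expanded into independent per-stage streams).
#' @param mode Calibration mode: `"normal"`, `"test1"` or `"test2"`.
#' @param n_detectors Modules in the simulated bank.
#' @param gain_sd,offset_sd_mm,reflectivity_sd Bank variability.
#' @param events_per_source Calibration events per source node.
#' @param n_uniformity Uniformity events per detector (test2).
#' @param reference_ids Donor detector ids (`test1`: 1 id; `test2`: 3 ids).
#' @param grid_n LUT pixels per side.
#' @param out_dir Output directory for run artifacts.
#' @param write_events_files Also persist the simulated event lists.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1, mode = c("normal", "test1", "test2"),
                       n_detectors = 4, gain_sd = 0.05, offset_sd_mm = 0.5,
                       reflectivity_sd = 0.02, events_per_source = 100,
                       n_uniformity = 50000, reference_ids = NULL,
                       grid_n = 200, out_dir = tempfile("monocal_run_"),
                       write_events_files = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(seed = as.integer(seed), mode = mode,
              n_detectors = as.integer(n_detectors), gain_sd = gain_sd,
              offset_sd_mm = offset_sd_mm, reflectivity_sd = reflectivity_sd,
              events_per_source = as.integer(events_per_source),
              n_uniformity = as.integer(n_uniformity),
              reference_ids = reference_ids, grid_n = as.integer(grid_n),
              out_dir = out_dir, write_events_files = write_events_files)
  ids <- sprintf("D%02d", seq_len(cfg$n_detectors))
  if (mode == "test1") {
    cfg$reference_ids <- cfg$reference_ids %||% ids[1]
    if (length(cfg$reference_ids) != 1 || !cfg$reference_ids %in% ids) {
      abort("mode 'test1' needs exactly one valid reference detector id.")
    }
  }
  if (mode == "test2") {
    if (is.null(cfg$reference_ids)) {
      abort("mode 'test2' requires `reference_ids` (nominally 3 donors).")
    }
    if (!all(cfg$reference_ids %in% ids) ||
        length(cfg$reference_ids) >= cfg$n_detectors) {
      abort("`reference_ids` must be a strict subset of the bank's ids.")
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the simulate -> estimate -> calibrate -> evaluate pipeline
#'
#' Simulates a detector bank, acquires calibration (and, for `test2`,
#' uniformity) data, calibrates in the requested mode, evaluates
#' correlation factors of accelerated modes against per-detector Normal
#' calibrations, and writes LUT directories, a JSON report and a manifest
#' (configuration, per-file hashes) under `config$out_dir`.  The same
#' configuration always reproduces identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the calibrations, the evaluation report
#'   and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- source_grid()
  bank <- make_detector_bank(config$n_detectors, config$gain_sd,
                             config$offset_sd_mm, config$reflectivity_sd,
                             seed = config$seed)
  ids <- names(bank)
  inform(sprintf("[simulate] bank of %d detectors", length(bank)))

  grid_est <- purrr::imap(bank, function(cfg, id) {
    ev <- with_stage_seed(config$seed, "grid", id, expr =
      simulate_grid_acquisition(grid, config$events_per_source, cfg))
    if (config$write_events_files) {
      write_events(ev, file.path(config$out_dir,
                                 sprintf("events_grid_%s.csv", id)))
    }
    estimate_events(ev)
  })

  inform("[calibrate] per-detector Normal calibrations")
  normal <- purrr::imap(grid_est, function(est, id) {
    normal_calibrate(est, grid, grid_n = config$grid_n, detector_id = id)
  })

  if (config$mode == "normal") {
    luts <- purrr::map(normal, "luts")
    eval_factors <- purrr::map(normal, "factors")
  } else if (config$mode == "test1") {
    luts <- test1_calibrate(normal[[config$reference_ids]]$luts, ids)
    eval_factors <- setNames(
      rep(list(normal[[config$reference_ids]]$factors), length(ids)), ids)
  } else {
    donors <- config$reference_ids
    uni <- purrr::imap(bank, function(cfg, id) {
      with_stage_seed(config$seed, "uniformity", id, expr =
        estimate_events(simulate_uniform_acquisition(config$n_uniformity,
                                                     cfg)))
    })
    ref_map <- average_calibration_maps(purrr::map(normal[donors], "map"))
    ref_corners <- average_corner_sets(
      purrr::map(uni[donors], detect_corners))
    res <- test2_calibrate(ref_map, ref_corners,
                           uni[setdiff(ids, donors)],
                           reference_factors = average_reference_factors(
                             purrr::map(normal[donors], "factors")),
                           grid_n = config$grid_n)
    # donors keep their own Normal calibration
    luts <- c(purrr::map(normal[donors], "luts"), res$luts)[ids]
    eval_factors <- c(purrr::map(normal[donors], "factors"),
                      res$factors)[ids]
  }

  inform("[evaluate] correlation factors vs Normal")
  cf_tbl <- purrr::map_dfr(ids, function(id) {
    dplyr::mutate(correlation_factors(eval_factors[[id]],
                                      normal[[id]]$factors),
                  detector_id = id)
  })
  report <- cf_summary(cf_tbl, .data$detector_id)

  for (id in names(luts)) {
    if (!is.null(luts[[id]])) {
      write_luts(luts[[id]], file.path(config$out_dir, paste0("luts_", id)))
    }
  }
  readr::write_csv(report, file.path(config$out_dir, "cf_report.csv"))
  jsonlite::write_json(
    list(report = report), file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("monocal")),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    files = lapply(setNames(nm = files), function(f) {
      unname(tools::md5sum(file.path(config$out_dir, f)))
    }))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  inform(sprintf("[done] artifacts in %s (%.1f s)",
                 config$out_dir,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(luts = luts, normal = normal, report = report,
                 manifest = manifest_path))
}
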