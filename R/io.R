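# Plain-text serialization of event lists, LUT sets and detector banks.
# Every file carries a schema line so readers can refuse mismatched or
# truncated inputs instead of silently misparsing.

EVENTS_SCHEMA <- "monocal-events v1 coords=crystal-center-mm depth=from-entrance-face"
LUT_SCHEMA <- "monocal-luts v1 range=[-1,1]^2"

#' Write / read event tables
#'
#' CSV with a commented schema header recording the format version and the
#' coordinate convention (planar mm from the crystal centre; depth from the
#' entrance face).  Round trips are exact to the printed precision (15
#' significant digits).
#'
#' @param events Event tibble (signal columns, optional truth columns).
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   tibble.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  writeLines(paste("#", EVENTS_SCHEMA), con)
  close(con)
  readr::write_csv(events, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste("#", EVENTS_SCHEMA))) {
    abort(sprintf("not a monocal event file: expected schema '%s', found '%s'.",
                  EVENTS_SCHEMA, sub("^# ?", "", first)))
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!any(grepl("^row_", names(out))) || !any(grepl("^col_", names(out)))) {
    abort("event file is missing row/column signal columns (truncated?).")
  }
  out
}

#' Write / read a LUT set
#'
#' A LUT set is stored as a directory holding the five tables as CSV
#' matrices (`lut_x.csv`, ..., `lut_energy.csv`) plus a `meta.json` with
#' the grid geometry, the generating centroids, the central photopeak and
#' provenance.
#'
#' @param luts A `lut_set`.
#' @param dir Directory to create/fill.
#' @return `write_luts` returns `dir` invisibly; `read_luts` the
#'   `lut_set`.
#' @export
write_luts <- function(luts, dir) {
  stopifnot(inherits(luts, "lut_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("x", "y", "doi1", "doi2", "energy")) {
    readr::write_csv(tibble::as_tibble(luts[[nm]], .name_repair = "minimal"),
                     file.path(dir, paste0("lut_", nm, ".csv")),
                     col_names = FALSE)
  }
  meta <- list(schema = LUT_SCHEMA, grid_n = luts$grid_n,
               detector_id = luts$detector_id,
               provenance = luts$provenance,
               central_peak = luts$central_peak,
               centroids = as.list(luts$centroids))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_luts
#' @export
read_luts <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("no meta.json in '%s'.", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, LUT_SCHEMA)) {
    abort(sprintf("LUT schema mismatch: expected '%s', found '%s'.",
                  LUT_SCHEMA, meta$schema %||% "<none>"))
  }
  tabs <- lapply(c("x", "y", "doi1", "doi2", "energy"), function(nm) {
    m <- as.matrix(readr::read_csv(file.path(dir, paste0("lut_", nm, ".csv")),
                                   col_names = FALSE, show_col_types = FALSE,
                                   progress = FALSE))
    dimnames(m) <- NULL
    if (any(dim(m) != meta$grid_n)) {
      abort(sprintf("LUT table '%s' has wrong shape (truncated?).", nm))
    }
    m
  })
  names(tabs) <- c("x", "y", "doi1", "doi2", "energy")
  structure(c(tabs, list(
    grid_n = as.integer(meta$grid_n),
    pixel_centers = lut_pixel_centers(meta$grid_n),
    centroids = tibble::as_tibble(meta$centroids),
    central_peak = meta$central_peak,
    detector_id = meta$detector_id,
    provenance = meta$provenance
  )), class = "lut_set")
}

#' Write / read a detector bank as a YAML configuration
#'
#' One block per detector with all [detector_config()] fields; gains are
#' stored row by row.
#'
#' @param bank A `detector_bank`.
#' @param path YAML file path.
#' @export
write_detector_bank <- function(bank, path) {
  blocks <- purrr::map(bank, function(cfg) {
    list(detector_id = cfg$detector_id,
         crystal_mm = cfg$crystal_mm,
         n_sensors = cfg$n_sensors,
         sensor_pitch_mm = cfg$sensor_pitch_mm,
         gains = apply(cfg$gains, 1, identity, simplify = FALSE),
         planar_offset_mm = cfg$planar_offset_mm,
         retro_reflectivity = cfg$retro_reflectivity,
         window_mm = cfg$window_mm,
         diffuse_fraction = cfg$diffuse_fraction,
         depth_coupling = cfg$depth_coupling,
         photon_yield = cfg$photon_yield,
         energy_channels_scale = cfg$energy_channels_scale,
         attenuation_mm_inv = cfg$attenuation_mm_inv,
         energy_fwhm = cfg$energy_fwhm,
         rng_seed = cfg$rng_seed)
  })
  yaml::write_yaml(list(schema = "monocal-bank v1", detectors = blocks),
                   path, precision = 12)
  invisible(path)
}

#' @rdname write_detector_bank
#' @export
read_detector_bank <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "monocal-bank v1")) {
    abort("not a monocal detector-bank file.")
  }
  bank <- purrr::map(raw$detectors, function(b) {
    detector_config(
      crystal_mm = unlist(b$crystal_mm),
      n_sensors = b$n_sensors,
      sensor_pitch_mm = b$sensor_pitch_mm,
      gains = t(sapply(b$gains, unlist)),
      planar_offset_mm = unlist(b$planar_offset_mm),
      retro_reflectivity = b$retro_reflectivity,
      window_mm = b$window_mm,
      diffuse_fraction = b$diffuse_fraction,
      depth_coupling = b$depth_coupling,
      photon_yield = b$photon_yield,
      energy_channels_scale = b$energy_channels_scale,
      attenuation_mm_inv = b$attenuation_mm_inv,
      energy_fwhm = b$energy_fwhm,
      rng_seed = b$rng_seed,
      detector_id = b$detector_id)
  })
  names(bank) <- purrr::map_chr(bank, "detector_id")
  structure(bank, class = c("detector_bank", "list"))
}
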