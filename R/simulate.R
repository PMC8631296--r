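# Solid-angle light transport for the monolithic block.
#
# A scintillation at (x, y, depth) illuminates the sensor plane directly
# (distance z = thickness - depth + window) and, via the retro-reflective
# entrance face, through a mirror image at z = thickness + depth + window,
# where `window` is the optical stand-off between crystal and sensors.  The lateral faces
# are black, so light walking off the sensor array is simply lost (edge
# truncation).  The expected photon count on sensor (i, j) is
#
#   gain_ij * yield * (E/511) * [ Omega(z_d) + r * Omega(z_m) ]
#
# mixed with a gain-independent uniform pedestal carrying a fixed fraction
# of the per-event total (diffuse reflections), and
#
# with Omega(z) = z * pitch^2 / (4 pi ((u_j - x)^2 + (v_i - y)^2 + z^2)^{3/2})
# the flat-sensor solid-angle fraction.  Rows index y, columns index x.

# Expected per-sensor counts for a block of events; returns an
# n_events x n_sensors^2 matrix in column-major sensor order
# (k = i + (j-1) * n, i = row/y, j = column/x).
expected_sensor_counts <- function(x_mm, y_mm, depth_mm, energy_kev, cfg) {
  n <- cfg$n_sensors
  u <- sensor_positions(cfg, "x")
  v <- sensor_positions(cfg, "y")
  thick <- cfg$crystal_mm[3]
  dx2 <- (outer(x_mm, u, "-"))^2          # events x n (column/x offsets)
  dy2 <- (outer(y_mm, v, "-"))^2          # events x n (row/y offsets)
  a <- cfg$sensor_pitch_mm^2 / (4 * pi)
  zd <- cfg$depth_coupling * (thick - depth_mm) + cfg$window_mm
  zm <- cfg$depth_coupling * (thick + depth_mm) + cfg$window_mm
  zd2 <- zd * zd
  zm2 <- zm * zm
  scale <- cfg$photon_yield * energy_kev / 511
  gain_vec <- as.vector(cfg$gains)        # column-major: matches k = i + (j-1)n
  lambda <- matrix(0, length(x_mm), n * n)
  r <- cfg$retro_reflectivity
  k <- 0L
  # per-sensor loop over length-N vectors: x * sqrt(x) instead of x^1.5,
  # and the direct term saturates at the hemisphere fraction 0.5 where the
  # flat-patch inverse-square approximation would diverge at the sensor
  # plane
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      d2 <- dx2[, j] + dy2[, i]
      td <- d2 + zd2
      tm <- d2 + zm2
      lambda[, k] <- (pmin(a * zd / (td * sqrt(td)), 0.5) +
                        (r * a) * zm / (tm * sqrt(tm))) * scale
    }
  }
  # diffuse pedestal: a fraction of the collected light is spread evenly
  # over the array (multiple reflections / optical crosstalk), conserving
  # the per-event total; sensor gains apply to whatever light arrives
  fd <- cfg$diffuse_fraction
  if (fd > 0) {
    lambda <- (1 - fd) * lambda + (fd / (n * n)) * rowSums(lambda)
  }
  lambda * rep(gain_vec, each = length(x_mm))
}

# Sum an events x n^2 sensor matrix into row and column signal tibble columns.
sum_rows_cols <- function(counts, cfg) {
  n <- cfg$n_sensors
  jj <- rep(seq_len(n), each = n)
  ii <- rep(seq_len(n), times = n)
  row_ind <- matrix(0, n^2, n); row_ind[cbind(seq_len(n^2), ii)] <- 1
  col_ind <- matrix(0, n^2, n); col_ind[cbind(seq_len(n^2), jj)] <- 1
  list(rows = counts %*% row_ind, cols = counts %*% col_ind)
}

signal_colnames <- function(cfg) {
  n <- cfg$n_sensors
  list(rows = sprintf("row_%02d", seq_len(n)),
       cols = sprintf("col_%02d", seq_len(n)))
}

#' Simulate SiPM row/column readout for a table of true events
#'
#' Applies the solid-angle light model (direct plus retro-reflected mirror
#' term, black lateral faces) to each true interaction, optionally samples
#' per-sensor Poisson photon counts, scales to ADC channels, and sums the
#' sensor matrix into the row and column signals provided by the readout.
#'
#' @param truth Data frame with columns `x_mm`, `y_mm`, `depth_mm`,
#'   `energy_keV` (crystal-centre planar frame; depth from entrance face).
#' @param cfg A [detector_config()].
#' @param poisson Sample per-sensor Poisson noise?  `FALSE` returns the
#'   expected (continuous) signals, useful for exact tests.
#' @param chunk_size Events per internal block (memory control).
#' @return `truth` with `detector_id` and signal columns `row_01..row_12`,
#'   `col_01..col_12` appended (channel units).
#' @export
#' @examples
#' tr <- tibble::tibble(x_mm = 0, y_mm = 0, depth_mm = 7, energy_keV = 511)
#' simulate_events(tr, detector_config(), poisson = FALSE)
simulate_events <- function(truth, cfg, poisson = TRUE, chunk_size = 20000L) {
  stopifnot(inherits(cfg, "detector_config"))
  req <- c("x_mm", "y_mm", "depth_mm", "energy_keV")
  if (!all(req %in% names(truth))) {
    abort(paste("`truth` must contain columns:", paste(req, collapse = ", ")))
  }
  half <- cfg$crystal_mm[1:2] / 2
  bad <- abs(truth$x_mm) > half[1] | abs(truth$y_mm) > half[2] |
    truth$depth_mm < 0 | truth$depth_mm > cfg$crystal_mm[3]
  if (any(bad)) {
    abort(sprintf("%d event(s) lie outside the crystal volume.", sum(bad)))
  }
  n_ev <- nrow(truth)
  nm <- signal_colnames(cfg)
  if (n_ev == 0) {
    empty <- matrix(numeric(0), 0, 2 * cfg$n_sensors,
                    dimnames = list(NULL, c(nm$rows, nm$cols)))
    return(dplyr::bind_cols(tibble::as_tibble(truth),
                            tibble::as_tibble(empty)))
  }
  out <- matrix(0, n_ev, 2 * cfg$n_sensors)
  starts <- seq(1L, n_ev, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n_ev)
    lambda <- expected_sensor_counts(truth$x_mm[idx], truth$y_mm[idx],
                                     truth$depth_mm[idx],
                                     truth$energy_keV[idx], cfg)
    counts <- if (poisson) {
      matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
    } else {
      lambda
    }
    rc <- sum_rows_cols(counts * cfg$energy_channels_scale, cfg)
    out[idx, ] <- cbind(rc$rows, rc$cols)
  }
  colnames(out) <- c(nm$rows, nm$cols)
  dplyr::bind_cols(
    tibble::as_tibble(truth),
    tibble::tibble(detector_id = cfg$detector_id),
    tibble::as_tibble(out))
}

# Inverse-CDF sample of interaction depth: exponential with rate `mu`
# truncated to [0, thickness].
sample_depth <- function(n, mu, thickness) {
  if (mu <= 0) return(runif(n, 0, thickness))
  u <- runif(n)
  -log(1 - u * (1 - exp(-mu * thickness))) / mu
}

# Mean of the truncated exponential on [0, L] (closed form, used in tests).
truncexp_mean <- function(mu, L) {
  1 / mu - L * exp(-mu * L) / (1 - exp(-mu * L))
}

sample_energy <- function(n, cfg) {
  pmax(50, rnorm(n, 511, 511 * cfg$energy_fwhm / (2 * sqrt(2 * log(2)))))
}

#' Simulate a collimated source-array calibration acquisition
#'
#' Draws `events_per_source` interactions per grid node: planar positions
#' uniform on the collimated beam disc around each mechanical node, depth
#' from the truncated exponential implied by the crystal attenuation, and
#' energy from the 511 keV Gaussian response.
#'
#' @param grid A [source_grid()].
#' @param events_per_source Events per source position (>= 1).
#' @param cfg A [detector_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @inheritParams simulate_events
#' @return Event tibble: truth columns, `node_i`, `node_j`, signal columns.
#' @export
simulate_grid_acquisition <- function(grid, events_per_source, cfg,
                                      poisson = TRUE, seed = NULL) {
  stopifnot(inherits(grid, "source_grid"), events_per_source >= 1)
  half <- cfg$crystal_mm[1:2] / 2
  r <- grid$beam_diameter_mm / 2
  if (max(abs(grid$nodes$mech_x_mm)) + r > half[1] ||
      max(abs(grid$nodes$mech_y_mm)) + r > half[2]) {
    abort("source grid extends beyond the crystal face.")
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- grid$nodes[rep(seq_len(nrow(grid$nodes)), each = events_per_source), ]
  n <- nrow(nodes)
  theta <- runif(n, 0, 2 * pi)
  rad <- r * sqrt(runif(n))
  truth <- tibble::tibble(
    node_i = nodes$node_i, node_j = nodes$node_j,
    x_mm = nodes$mech_x_mm + rad * cos(theta),
    y_mm = nodes$mech_y_mm + rad * sin(theta),
    depth_mm = sample_depth(n, cfg$attenuation_mm_inv, cfg$crystal_mm[3]),
    energy_keV = sample_energy(n, cfg))
  simulate_events(truth, cfg, poisson = poisson)
}

#' Simulate a uniform-irradiation (flood) acquisition
#'
#' Planar positions uniform over the crystal face; depth and energy as in
#' [simulate_grid_acquisition()].  This emulates the uniformity acquisition
#' obtained with a large uniform activity phantom.
#'
#' @param n_events Number of events (> 0).
#' @inheritParams simulate_grid_acquisition
#' @return Event tibble with truth and signal columns.
#' @export
simulate_uniform_acquisition <- function(n_events, cfg, poisson = TRUE,
                                         seed = NULL) {
  if (n_events <= 0) abort("`n_events` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  half <- cfg$crystal_mm[1:2] / 2
  truth <- tibble::tibble(
    x_mm = runif(n_events, -half[1], half[1]),
    y_mm = runif(n_events, -half[2], half[2]),
    depth_mm = sample_depth(n_events, cfg$attenuation_mm_inv, cfg$crystal_mm[3]),
    energy_keV = sample_energy(n_events, cfg))
  simulate_events(truth, cfg, poisson = poisson)
}
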