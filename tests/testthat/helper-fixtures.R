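# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default detector and grid used across tests
test_cfg <- function(...) detector_config(...)

# a Normal-calibrated default detector (moderate statistics)
fx_normal <- function() fixture("normal", function() {
  cfg <- test_cfg()
  g <- source_grid()
  est <- suppressMessages(suppressWarnings(
    estimate_events(simulate_grid_acquisition(g, 250, cfg, seed = 101))))
  list(cfg = cfg, grid = g, est = est,
       cal = suppressWarnings(normal_calibrate(est, g, grid_n = 120)))
})

# a small uniformity acquisition for the same detector
fx_uniform <- function() fixture("uniform", function() {
  suppressMessages(estimate_events(
    simulate_uniform_acquisition(1e5, test_cfg(), seed = 202)))
})

# signal tibble helper: one event from named row/col vectors
signals_tbl <- function(rows, cols) {
  stopifnot(length(rows) == length(cols))
  n <- length(rows)
  tibble::as_tibble(as.list(setNames(
    c(rows, cols),
    c(sprintf("row_%02d", seq_len(n)), sprintf("col_%02d", seq_len(n))))))
}

# single-node calibration map for arithmetic checks
new_toy_map <- function(meas_x, mech_x) {
  nodes <- tibble::tibble(node_i = 0L, node_j = 0L,
                          mech_x = mech_x, mech_y = 0,
                          x = meas_x, y = 0, n_events = 100L)
  monocal:::new_calibration_map(nodes, source_grid())
}
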