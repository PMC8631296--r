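test_that("noise-free flood maps localize to the per-node event means", {
  cfg <- test_cfg()
  g <- source_grid()
  # degenerate acquisition: no photon noise, fixed depth and energy, so
  # each source is a tight, fully separable cluster
  set.seed(21)
  nodes <- g$nodes[rep(seq_len(121), each = 60), ]
  r <- g$beam_diameter_mm / 2 * sqrt(runif(nrow(nodes)))
  th <- runif(nrow(nodes), 0, 2 * pi)
  truth <- tibble::tibble(node_i = nodes$node_i, node_j = nodes$node_j,
                          x_mm = nodes$mech_x_mm + r * cos(th),
                          y_mm = nodes$mech_y_mm + r * sin(th),
                          depth_mm = 7.5, energy_keV = 511)
  est <- estimate_events(simulate_events(truth, cfg, poisson = FALSE))
  cm <- localize_sources(est, g, min_events = 30)
  truth_means <- est |>
    dplyr::group_by(.data$node_i, .data$node_j) |>
    dplyr::summarise(x = mean(.data$x_norm), y = mean(.data$y_norm),
                     .groups = "drop") |>
    dplyr::arrange(.data$node_i, .data$node_j)
  got <- dplyr::arrange(cm$nodes, .data$node_i, .data$node_j)
  expect_lt(max(abs(got$x - truth_means$x)), 1e-3)
  expect_lt(max(abs(got$y - truth_means$y)), 1e-3)
})

test_that("centroids of a distorted detector match the truth-label oracle", {
  cfg <- test_cfg(gains = matrix(exp(rnorm(144, 0, 0.05)), 12, 12))
  g <- source_grid()
  est <- suppressMessages(estimate_events(
    simulate_grid_acquisition(g, 500, cfg, seed = 22)))
  cm <- suppressWarnings(localize_sources(est, g))
  oracle <- est |>
    dplyr::group_by(.data$node_i, .data$node_j) |>
    dplyr::summarise(x = mean(.data$x_norm), y = mean(.data$y_norm),
                     .groups = "drop")
  j <- dplyr::left_join(cm$nodes, oracle, by = c("node_i", "node_j"),
                        suffix = c("", "_oracle"))
  dev <- sqrt((j$x - j$x_oracle)^2 + (j$y - j$y_oracle)^2)
  interior <- j$node_i %in% 2:8 & j$node_j %in% 2:8
  # interior clusters are fully separable; clusters closer to the border
  # overlap through their depth-driven tails, so nearest-centroid and
  # truth-label assignments legitimately differ there
  expect_lt(max(dev[interior]), 0.01)
  expect_lt(max(dev), 0.12)
})

test_that("an unpopulated grid node is reported by index", {
  cfg <- test_cfg()
  g <- source_grid()
  est <- estimate_events(simulate_grid_acquisition(g, 60, cfg, seed = 23))
  holed <- dplyr::filter(est, !(.data$node_i == 5 & .data$node_j == 5))
  expect_error(localize_sources(holed, g, min_events = 30), "\\(5,5\\)")
})

test_that("the Voronoi partition has 121 cells matching brute force", {
  cal <- fx_normal()$cal
  part <- build_voronoi(cal$map)
  expect_equal(part$n_cells, 121)
  set.seed(4)
  px <- runif(1e4, -1, 1)
  py <- runif(1e4, -1, 1)
  got <- part$cell(px, py)
  cx <- cal$map$nodes$x
  cy <- cal$map$nodes$y
  brute <- vapply(seq_along(px), function(i) {
    which.min((px[i] - cx)^2 + (py[i] - cy)^2)
  }, integer(1))
  expect_equal(got, brute)
  # each centroid belongs to its own cell
  expect_equal(part$cell(cx, cy), seq_len(121))
  dup <- cal$map$nodes
  dup$x[2] <- dup$x[1]
  dup$y[2] <- dup$y[1]
  expect_error(build_voronoi(dup), "duplicate")
})

test_that("planar factors are the mechanical-minus-measured deviations", {
  cal <- fx_normal()$cal
  fac <- compute_xy_factors(cal$map)
  expect_equal(fac$f_x, cal$map$nodes$mech_x - cal$map$nodes$x)
  # applying the factors to the centroids reproduces mechanical positions
  expect_equal(cal$map$nodes$x + fac$f_x, cal$map$nodes$mech_x)
  expect_equal(cal$map$nodes$y + fac$f_y, cal$map$nodes$mech_y)
  # hand arithmetic
  toy <- new_toy_map(meas_x = 0.80, mech_x = 0.92)
  expect_equal(compute_xy_factors(toy)$f_x[1], 0.12)
})

test_that("energy correction equalizes photopeaks across cells", {
  # identical spectra in every cell: correction ratio 1 everywhere
  set.seed(8)
  est <- tibble::tibble(cell = rep(1:4, each = 2000),
                        E_channels = rep(rnorm(2000, 6000, 300), 4))
  f <- compute_energy_factors(est, 4)
  expect_lt(max(abs(f / f[1] - 1)), 0.01)
  # a cell at 5000 ch corrected to a 6000 ch reference lands at 6000
  expect_equal(5000 * 6000 / 5000, 6000)

  # detector with lower light yield at the edge columns: calibration
  # shrinks the photopeak spread by an order of magnitude
  gains <- matrix(1, 12, 12)
  gains[, c(1, 2, 11, 12)] <- 0.9
  cfg <- test_cfg(gains = gains)
  g <- source_grid()
  est2 <- suppressMessages(estimate_events(
    simulate_grid_acquisition(g, 250, cfg, seed = 77)))
  cal <- suppressWarnings(normal_calibrate(est2, g, grid_n = 100))
  calib <- calibrate_events(est2, cal$luts)
  part <- build_voronoi(cal$map)
  cells <- part$cell(calib$x_norm, calib$y_norm)
  peaks <- function(e) {
    vapply(split(e, cells), function(v) {
      if (length(v) < 50) return(NA_real_)
      monocal:::find_photopeak(v)
    }, numeric(1))
  }
  spread <- function(p) sd(p, na.rm = TRUE) / mean(p, na.rm = TRUE)
  before <- suppressWarnings(spread(peaks(calib$E_channels)))
  after <- suppressWarnings(spread(peaks(calib$E_cal)))
  expect_lt(after, 0.025)
  expect_lt(after, before / 5)
})

test_that("DOI limit fits recover a known smoothed box", {
  set.seed(12)
  x <- runif(1e4, 2, 6) + rnorm(1e4, 0, 0.1)
  f <- fit_doi_limits(x)
  expect_lt(abs(f$a - 2) / 2, 0.05)
  expect_lt(abs(f$b - 6) / 6, 0.05)
  expect_lt(abs(f$sigma_int - 0.1) / 0.1, 0.25)
  expect_true(f$f_doi1 < f$a && f$a < f$b && f$b < f$f_doi2)

  # sharp box: limits land at the box ends within a bin width
  x2 <- runif(5000, 2, 6)
  f2 <- fit_doi_limits(x2)
  bw <- 4 / 48
  expect_lt(abs(f2$a - 2), 2 * bw)
  expect_lt(abs(f2$b - 6), 2 * bw)

  expect_error(fit_doi_limits(rep(3, 100)), "degenerate")
})

test_that("DOI calibration is the anchored affine map", {
  expect_equal(calibrate_doi(1.5, 1.5, 4.5), 0)
  expect_equal(calibrate_doi(4.5, 1.5, 4.5), 15)
  expect_equal(calibrate_doi(3, 1.5, 4.5), 7.5)
  # clipping
  expect_equal(calibrate_doi(c(0, 10), 1.5, 4.5), c(0, 15))
  expect_error(calibrate_doi(2, 3, 3), "f_doi1 < f_doi2")
})

test_that("rasterized LUTs agree with nearest-centroid lookup", {
  cal <- fx_normal()$cal
  luts <- cal$luts
  expect_equal(luts$grid_n, 120)
  # a pixel at a centroid carries that cell's factors
  fac <- cal$factors
  k <- 61
  lk <- lut_lookup(luts, cal$map$nodes$x[k], cal$map$nodes$y[k])
  expect_equal(lk$lut_x, fac$f_x[k])
  expect_equal(lk$lut_energy, fac$f_e[k])
  # brute force on random pixels
  set.seed(15)
  px <- runif(1e3, -1, 1)
  py <- runif(1e3, -1, 1)
  lk2 <- lut_lookup(luts, px, py)
  ctr <- luts$pixel_centers
  ix <- pmin(pmax(ceiling((px + 1) / 2 * luts$grid_n), 1), luts$grid_n)
  iy <- pmin(pmax(ceiling((py + 1) / 2 * luts$grid_n), 1), luts$grid_n)
  cell <- vapply(seq_along(px), function(i) {
    which.min((ctr[ix[i]] - cal$map$nodes$x)^2 +
                (ctr[iy[i]] - cal$map$nodes$y)^2)
  }, integer(1))
  expect_equal(lk2$lut_x, fac$f_x[cell])
  expect_lte(length(unique(as.vector(luts$x))), 121)
  expect_error(rasterize_luts(fac, cal$map, grid_n = 1), "at least 2")
})

test_that("event calibration applies the LUTs and conserves events", {
  cal <- fx_normal()$cal
  est <- fx_normal()$est
  out <- calibrate_events(est, cal$luts)
  expect_equal(nrow(out), nrow(est))
  # events at measured centroids come back at mechanical positions (mm)
  ctr_est <- tibble::tibble(
    x_norm = cal$map$nodes$x, y_norm = cal$map$nodes$y,
    E_channels = 6000, doi_raw = 4)
  ctr_out <- calibrate_events(ctr_est, cal$luts)
  expect_lt(max(abs(ctr_out$x_cal_mm - cal$map$nodes$mech_x * 25)), 0.25)
  expect_lt(max(abs(ctr_out$y_cal_mm - cal$map$nodes$mech_y * 25)), 0.25)
  # identity LUTs: output is input scaled to mm
  id_luts <- cal$luts
  id_luts$x[] <- 0
  id_luts$y[] <- 0
  id_luts$energy[] <- id_luts$central_peak
  id_out <- calibrate_events(est, id_luts)
  expect_equal(id_out$x_cal_mm, est$x_norm * 25)
  expect_equal(id_out$E_cal, est$E_channels)
  # off-map events are clamped and flagged
  off <- tibble::tibble(x_norm = 1.2, y_norm = 0, E_channels = 1,
                        doi_raw = 4)
  expect_true(calibrate_events(off, cal$luts)$flagged)
})

test_that("calibrating the calibration acquisition recovers the grid", {
  fx <- fx_normal()
  out <- calibrate_events(fx$est, fx$cal$luts)
  rec <- tibble::tibble(node_i = fx$est$node_i, node_j = fx$est$node_j,
                        x = out$x_cal_mm, y = out$y_cal_mm) |>
    dplyr::group_by(.data$node_i, .data$node_j) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                     .groups = "drop") |>
    dplyr::left_join(fx$grid$nodes, by = c("node_i", "node_j"))
  interior <- rec$node_i %in% 1:9 & rec$node_j %in% 1:9
  rms <- sqrt(mean((rec$x[interior] - rec$mech_x_mm[interior])^2 +
                     (rec$y[interior] - rec$mech_y_mm[interior])^2))
  expect_lt(rms, 1)
})
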