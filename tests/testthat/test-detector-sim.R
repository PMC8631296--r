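test_that("noise-free signals are symmetric for a centred event", {
  cfg <- test_cfg()
  tr <- tibble::tibble(x_mm = 0, y_mm = 0, depth_mm = 7.5, energy_keV = 511)
  ev <- simulate_events(tr, cfg, poisson = FALSE)
  rows <- as.numeric(ev[1, sprintf("row_%02d", 1:12)])
  cols <- as.numeric(ev[1, sprintf("col_%02d", 1:12)])
  expect_equal(rows, rev(rows))
  expect_equal(cols, rev(cols))
  expect_equal(rows, cols)
})

test_that("signal model is linear in gains and energy with noise off", {
  tr <- tibble::tibble(x_mm = c(-8, 3), y_mm = c(5, -12),
                       depth_mm = c(2, 11), energy_keV = c(511, 511))
  cfg1 <- test_cfg()
  cfg2 <- test_cfg(gains = 2)
  e1 <- simulate_events(tr, cfg1, poisson = FALSE)
  e2 <- simulate_events(tr, cfg2, poisson = FALSE)
  sig <- c(sprintf("row_%02d", 1:12), sprintf("col_%02d", 1:12))
  expect_equal(as.matrix(e2[sig]), 2 * as.matrix(e1[sig]))
  tr_half <- dplyr::mutate(tr, energy_keV = energy_keV / 2)
  e3 <- simulate_events(tr_half, cfg1, poisson = FALSE)
  expect_equal(as.matrix(e3[sig]), as.matrix(e1[sig]) / 2)
})

test_that("light concentration Imax/E is extremal at the two crystal faces", {
  # closed-form model evaluation over a depth sweep, noise off
  cfg <- test_cfg(retro_reflectivity = 0)
  depths <- seq(0.1, 14.9, length.out = 15)
  tr <- tibble::tibble(x_mm = 0, y_mm = 0, depth_mm = depths,
                       energy_keV = 511)
  est <- estimate_events(simulate_events(tr, cfg, poisson = FALSE))
  conc <- 1 / est$doi_raw          # Imax / E
  expect_equal(which.max(conc), length(depths))   # at the sensor plane
  expect_equal(which.min(conc), 1)                # at the entrance face
  expect_true(all(diff(conc) > 0))                # monotone in depth
})

test_that("events outside the crystal are rejected", {
  tr <- tibble::tibble(x_mm = 26, y_mm = 0, depth_mm = 5, energy_keV = 511)
  expect_error(simulate_events(tr, test_cfg()), "outside the crystal")
  tr2 <- tibble::tibble(x_mm = 0, y_mm = 0, depth_mm = 16, energy_keV = 511)
  expect_error(simulate_events(tr2, test_cfg()), "outside the crystal")
})

test_that("grid acquisition produces the expected event structure", {
  g <- source_grid()
  ev <- simulate_grid_acquisition(g, 100, test_cfg(), seed = 1)
  expect_equal(nrow(ev), 121 * 100)
  # every node has events inside its beam disc
  near <- ev |>
    dplyr::left_join(g$nodes, by = c("node_i", "node_j")) |>
    dplyr::mutate(r = sqrt((.data$x_mm - .data$mech_x_mm)^2 +
                             (.data$y_mm - .data$mech_y_mm)^2)) |>
    dplyr::group_by(.data$node_i, .data$node_j) |>
    dplyr::summarise(n_in = sum(.data$r <= g$beam_diameter_mm / 2),
                     .groups = "drop")
  expect_true(all(near$n_in >= 1))
  expect_error(
    simulate_grid_acquisition(source_grid(n = 11, pitch_mm = 5), 10,
                              test_cfg()),
    "beyond the crystal")
})

test_that("sampled depths follow the truncated exponential", {
  mu <- 0.087
  L <- 15
  set.seed(7)
  d <- monocal:::sample_depth(1e5, mu, L)
  expect_true(all(d >= 0 & d <= L))
  m_closed <- monocal:::truncexp_mean(mu, L)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - m_closed), 3 * se)
  # extreme attenuation: all depths collapse to the entrance face
  d2 <- monocal:::sample_depth(1e3, 1e6, L)
  expect_true(all(d2 < 1e-4))
})

test_that("uniform acquisition is planar-uniform and errors on n <= 0", {
  ev <- simulate_uniform_acquisition(1e5, test_cfg(), seed = 3)
  # chi-square uniformity over a 5 x 5 binning of the true positions
  bx <- cut(ev$x_mm, seq(-25, 25, length.out = 6))
  by <- cut(ev$y_mm, seq(-25, 25, length.out = 6))
  p <- stats::chisq.test(table(bx, by))$p.value
  expect_gt(p, 0.01)
  expect_error(simulate_uniform_acquisition(0, test_cfg()), "positive")
})

test_that("measured uniformity flood accumulates events toward the edges", {
  est <- fx_uniform()
  h <- flood_histogram(est, 64)
  prof <- rowSums(h$counts)
  occ <- which(prof > 0)
  extent <- range(h$x_centers[occ])
  centred <- abs(h$x_centers - mean(extent)) / (diff(extent) / 2)
  interior <- median(prof[occ][centred[occ] < 0.5])
  peak_at <- centred[which.max(prof)]
  # the accumulation maximum sits in the outer band and clearly exceeds
  # the interior plateau
  expect_gt(peak_at, 0.55)
  expect_gt(max(prof) / interior, 1.1)
})

test_that("detector banks reproduce the base config at zero variability", {
  base <- test_cfg()
  bank <- make_detector_bank(4, 0, 0, 0, base, seed = 5)
  expect_length(bank, 4)
  for (cfg in bank) {
    expect_equal(cfg$gains, base$gains)
    expect_equal(cfg$planar_offset_mm, base$planar_offset_mm)
    expect_equal(cfg$retro_reflectivity, base$retro_reflectivity)
  }
})

test_that("bank gain spread matches the requested standard deviation", {
  bank <- make_detector_bank(24, gain_sd = 0.05, seed = 9)
  gains <- unlist(purrr::map(bank, function(cfg) as.vector(cfg$gains)))
  expect_lt(abs(sd(gains) - 0.05) / 0.05, 0.2)   # 24 x 144 draws
  expect_length(bank, 24)
})

test_that("identical seeds give bitwise-identical event lists", {
  g <- source_grid()
  e1 <- simulate_grid_acquisition(g, 20, test_cfg(), seed = 42)
  e2 <- simulate_grid_acquisition(g, 20, test_cfg(), seed = 42)
  expect_identical(e1, e2)
})

test_that("software collimation matches the brute-force angle cut", {
  expect_equal(nrow(filter_lors(tibble::tibble(
    ax = 0, ay = 0, bx = 0, by = 0, separation_mm = 200))), 1)
  # 10 mm transverse offset at 200 mm separation is 2.86 deg: rejected
  expect_equal(nrow(filter_lors(tibble::tibble(
    ax = 10, ay = 0, bx = 0, by = 0, separation_mm = 200))), 0)
  set.seed(11)
  off <- runif(1000, 0, 10)
  lors <- tibble::tibble(ax = off, ay = 0, bx = 0, by = 0,
                         separation_mm = 200)
  kept <- filter_lors(lors)
  brute <- sum(off <= 200 * tan(1.2 * pi / 180))
  expect_equal(nrow(kept), brute)
  expect_error(filter_lors(tibble::tibble(ax = 0, ay = 0, bx = 0, by = 0,
                                          separation_mm = 0)),
               "positive")
})
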