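test_that("sharing a donor LUT set copies it to every detector", {
  luts <- fx_normal()$cal$luts
  ids <- sprintf("D%02d", 1:24)
  shared <- test1_calibrate(luts, ids)
  expect_length(shared, 24)
  for (l in shared) {
    expect_equal(l$x, luts$x)
    expect_equal(l$energy, luts$energy)
  }
  expect_match(shared[[5]]$provenance, "shared")
  # CF of the donor against itself is 1 for all five quantities
  fac <- fx_normal()$cal$factors
  s <- cf_summary(correlation_factors(fac, fac))
  expect_equal(s$cf_mean, rep(1, 5))
})

test_that("calibration-map averaging is the node-wise mean", {
  fx <- fx_normal()
  m <- fx$cal$map
  expect_warning(avg1 <- average_calibration_maps(list(m)), "3 are typical")
  expect_equal(avg1$nodes$x, m$nodes$x)
  shift <- function(m, dx) {
    m$nodes$x <- m$nodes$x + dx
    m
  }
  avg <- average_calibration_maps(list(m, shift(m, 0.01), shift(m, 0.02)))
  expect_equal(avg$nodes$x, m$nodes$x + 0.01)
  # node-wise mean on explicit values
  toy <- function(x) new_toy_map(meas_x = x, mech_x = 0.5)
  a <- average_calibration_maps(list(toy(0.1), toy(0.2), toy(0.3)))
  expect_equal(a$nodes$x, 0.2)
})

test_that("averaging reference maps reduces per-node variance", {
  cfg_bank <- make_detector_bank(3, gain_sd = 0.05, offset_sd_mm = 0.3,
                                 seed = 60)
  g <- source_grid()
  maps <- purrr::map(cfg_bank, function(cfg) {
    suppressWarnings(localize_sources(suppressMessages(
      estimate_events(simulate_grid_acquisition(g, 150, cfg,
                                                seed = cfg$rng_seed))), g))
  })
  avg <- average_calibration_maps(unname(maps))
  dev <- function(m) mean((m$nodes$x - m$nodes$mech_x)^2 +
                            (m$nodes$y - m$nodes$mech_y)^2)
  devs <- purrr::map_dbl(maps, dev)
  # the averaged map is no farther from the mechanical grid than the
  # worst single map (variance reduction of the random component)
  expect_lte(dev(avg), max(devs))
})

test_that("corners of a synthetic square flood are recovered", {
  bins <- 128
  ctr <- monocal:::lut_pixel_centers(bins)
  counts <- matrix(0L, bins, bins)
  on_edge <- abs(abs(ctr) - 0.9) < 0.02
  inside <- abs(ctr) <= 0.9
  counts[on_edge, inside] <- counts[on_edge, inside] + 400L
  counts[inside, on_edge] <- counts[inside, on_edge] + 400L
  counts[inside, inside] <- counts[inside, inside] + 40L
  h <- structure(list(counts = counts, x_centers = ctr, y_centers = ctr),
                 class = "flood_hist")
  co <- detect_corners(h)
  bw <- 2 / bins
  expect_lt(max(abs(abs(co$x) - 0.9)), 2 * bw)
  expect_lt(max(abs(abs(co$y) - 0.9)), 2 * bw)
  expect_equal(co$corner, c("TL", "TR", "BL", "BR"))

  # rotating the histogram by 90 degrees permutes the corners
  h90 <- h
  h90$counts <- t(counts)[bins:1, ]
  co90 <- detect_corners(h90)
  expect_equal(sort(round(co90$x, 2)), sort(round(co$x, 2)))
})

test_that("corner detection is repeatable across acquisitions", {
  cfg <- test_cfg()
  cs <- sapply(1:4, function(s) {
    est <- suppressMessages(estimate_events(
      simulate_uniform_acquisition(1.2e5, cfg, seed = 300 + s)))
    co <- detect_corners(est)
    c(co$x, co$y)
  })
  expect_lt(max(apply(cs, 1, sd)), 0.01)
})

test_that("corner shifts follow the stated sign convention", {
  co <- detect_corners(fx_uniform())
  z <- corner_shifts(co, co)
  expect_equal(z$dx, rep(0, 4))
  expect_equal(z$dy, rep(0, 4))
  moved <- co
  moved$x <- moved$x + 0.02
  sh <- corner_shifts(moved, co)
  expect_equal(sh$dx, rep(-0.02, 4))
  # applying the shifts to the detector corners reproduces the reference
  expect_equal(moved$x + sh$dx, co$x)
  expect_equal(moved$y + sh$dy, co$y)
})

test_that("shift-map interpolation is exact at generators and continuous", {
  co <- detect_corners(fx_uniform())
  sh <- corner_shifts(co, co)
  sh$dx <- c(0.01, 0.02, -0.01, 0.03)
  sh$dy <- c(0, -0.01, 0.02, 0.01)
  sm <- interpolate_shift_map(co, sh, grid_n = 80)
  at_corners <- sm$at(co$x, co$y)
  expect_equal(at_corners$dx, sh$dx, tolerance = 1e-6)
  expect_equal(at_corners$dy, sh$dy, tolerance = 1e-6)
  # four equal shifts give a constant map
  shc <- sh
  shc$dx <- rep(0.02, 4)
  shc$dy <- rep(-0.01, 4)
  smc <- interpolate_shift_map(co, shc, grid_n = 40)
  expect_equal(range(smc$dx), c(0.02, 0.02))
  expect_equal(range(smc$dy), c(-0.01, -0.01))
  # value at the bilinear centre is the mean of the four shifts
  q <- monocal:::quad_from_corners(co)
  centre <- (q$BL + q$BR + q$TL + q$TR) / 4
  at_c <- sm$at(centre[1], centre[2])
  expect_equal(at_c$dx, mean(sh$dx), tolerance = 1e-6)
  expect_equal(at_c$dy, mean(sh$dy), tolerance = 1e-6)
  # continuity: no jumps between neighbouring pixels of a fine raster
  expect_lt(max(abs(diff(sm$dx))), 0.004)
  expect_lt(max(abs(t(diff(t(sm$dx))))), 0.004)
  # degenerate quadrilateral
  bad <- co
  bad$x <- c(0, 0, 0, 0)
  bad$y <- c(1, 1, -1, -1)
  expect_error(interpolate_shift_map(bad, sh, 10), "degenerate")
})

test_that("shift-map calibration reduces to Normal for the reference detector", {
  fx <- fx_normal()
  est_u <- fx_uniform()
  co <- detect_corners(est_u)
  res <- suppressWarnings(test2_calibrate(fx$cal$map, co,
                                          list(D01 = est_u),
                                          make_luts = FALSE))
  expect_true(res$report$ok)
  expect_lt(res$report$max_abs_shift, 1e-12)  # same events, same corners
  expect_equal(res$factors$D01$f_x, fx$cal$factors$f_x)
  expect_equal(res$factors$D01$f_y, fx$cal$factors$f_y)
})

test_that("a failing detector is reported and the rest continue", {
  fx <- fx_normal()
  est_u <- fx_uniform()
  co <- detect_corners(est_u)
  broken <- dplyr::filter(est_u, abs(.data$x_norm) < 0.1,
                          abs(.data$y_norm) < 0.1)   # no edge structure
  expect_warning(
    res <- test2_calibrate(fx$cal$map, co,
                           list(D01 = est_u, D02 = broken),
                           make_luts = FALSE),
    "failed for 1 detector")
  expect_true(res$report$ok[res$report$detector_id == "D01"])
  expect_false(res$report$ok[res$report$detector_id == "D02"])
  expect_named(res$factors, "D01")
})
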