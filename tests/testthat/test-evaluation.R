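make_factors <- function(f_x, f_y = f_x, f_e = 6000, f_doi1 = 2, f_doi2 = 6) {
  n <- length(f_x)
  tibble::tibble(cell = seq_len(n), node_i = 0L, node_j = 0L,
                 f_x = f_x, f_y = f_y, f_e = f_e,
                 doi_a = f_doi1 + 0.1, doi_b = f_doi2 - 0.1,
                 doi_sigma = 0.1, f_doi1 = f_doi1, f_doi2 = f_doi2)
}

test_that("correlation factors are per-cell ratios with stable means", {
  f <- make_factors(seq(0.02, 0.2, length.out = 10))
  s <- cf_summary(correlation_factors(f, f))
  expect_equal(s$cf_mean, rep(1, 5))
  expect_equal(s$n_excluded, rep(0L, 5))

  # energy arithmetic: 5400 over 6000 everywhere
  f2 <- make_factors(f$f_x, f_e = 5400)
  s2 <- cf_summary(correlation_factors(f2, f))
  expect_equal(s2$cf_mean[s2$quantity == "Energy"], 0.9)

  # near-zero reference planar factors are excluded and counted
  f3 <- make_factors(c(1e-4, seq(0.02, 0.2, length.out = 9)))
  cf3 <- correlation_factors(make_factors(f3$f_x * 1.1), f3)
  s3 <- cf_summary(cf3)
  expect_equal(s3$n_excluded[s3$quantity == "X"], 1L)

  expect_error(correlation_factors(f, make_factors(1:3 / 10)),
               "mismatch")
})

test_that("CF means equal a brute-force loop and scale covariantly", {
  fac <- fx_normal()$cal$factors
  set.seed(19)
  test_fac <- fac
  for (col in c("f_x", "f_y", "f_e", "f_doi1", "f_doi2")) {
    test_fac[[col]] <- fac[[col]] * (1 + rnorm(nrow(fac), 0, 0.03))
  }
  cf <- correlation_factors(test_fac, fac)
  s <- cf_summary(cf)
  cols <- c(X = "f_x", Y = "f_y", DOI1 = "f_doi1", DOI2 = "f_doi2",
            Energy = "f_e")
  for (q in names(cols)) {
    r <- test_fac[[cols[q]]] / fac[[cols[q]]]
    if (q %in% c("X", "Y")) r <- r[abs(fac[[cols[q]]]) >= 1e-3]
    expect_equal(s$cf_mean[s$quantity == q], mean(r))
  }
  # multiplying all test factors by k multiplies CF by k
  scaled <- test_fac
  for (col in cols) scaled[[col]] <- scaled[[col]] * 2
  s2 <- cf_summary(correlation_factors(scaled, fac))
  expect_equal(s2$cf_mean, 2 * s$cf_mean)
})

test_that("profile FWHM matches closed forms", {
  set.seed(21)
  x <- rnorm(1e5, 0, 1)
  expect_lt(abs(profile_fwhm(x, 0.25) - 2 * sqrt(2 * log(2))), 0.05)
  # box of width w
  w <- 4
  b <- runif(2e5, -w / 2, w / 2)
  expect_lt(abs(profile_fwhm(b, 0.1) - w), 0.15)
  # two separated peaks: warning, widest span returned
  mix <- c(rnorm(5e4, -5, 0.5), rnorm(5e4, 5, 0.5))
  expect_warning(f <- profile_fwhm(mix, 0.25), "multiple peaks")
  expect_gt(f, 8)
  expect_error(profile_fwhm(rnorm(50), 0.1), "at least 100")
})

test_that("CNR and contrast match voxel-level recomputation", {
  # arithmetic case: hot 10, background level 2, background SD 1
  img <- array(2, c(4, 4, 4))
  img[1, 1, 1] <- 10
  bg <- which(img == 2)
  set.seed(5)
  img[bg] <- 2 + scale(rnorm(length(bg)))[, 1]   # mean 2, sd 1 exactly
  hot <- list(1L)
  r <- cnr(img, hot, list(bg))
  expect_equal(r$cnr, 8)
  expect_equal(contrast(img, hot, 2)$contrast_pct, 80)
  expect_equal(contrast(img, hot, 0)$contrast_pct, 100)

  # random-image oracle
  set.seed(6)
  img2 <- array(rpois(8000, 5), c(20, 20, 20))
  hot2 <- list(1:50, 51:100)
  bg2 <- lapply(0:11, function(k) 200 + k * 60 + 1:40)
  r2 <- cnr(img2, hot2, bg2)
  bgv <- img2[unlist(bg2)]
  for (i in 1:2) {
    expect_equal(r2$cnr[i],
                 (mean(img2[hot2[[i]]]) - mean(bgv)) / sd(bgv))
  }
  c2 <- contrast(img2, hot2, bg2)
  expect_equal(c2$contrast_pct,
               100 * (r2$hot_mean - mean(bgv)) / r2$hot_mean)

  # hot equal to background distribution: CNR near zero
  same <- cnr(img2, list(2001:2400), bg2)
  expect_lt(abs(same$cnr), 1)

  expect_error(cnr(array(1, c(3, 3, 3)), list(1:2), list(3:4)),
               "standard deviation")
  expect_error(cnr(img2, list(1:5), list(3:10)), "disjoint")
})

test_that("the noiseless ratio-38 phantom has the closed-form contrast", {
  ph <- synthetic_iq_phantom(ratio = 38, background = 10, poisson = FALSE)
  expect_length(ph$hot_vois, 6)
  expect_length(ph$background_vois, 12)
  ct <- contrast(ph$image, ph$hot_vois, ph$background_vois)
  expect_equal(ct$contrast_pct, rep(100 * 37 / 38, 6), tolerance = 1e-10)
  # with Poisson noise the per-rod CNR matches the voxel-level oracle
  set.seed(9)
  ph2 <- synthetic_iq_phantom(ratio = 38, background = 10, poisson = TRUE)
  r <- cnr(ph2$image, ph2$hot_vois, ph2$background_vois)
  bgv <- ph2$image[unlist(ph2$background_vois)]
  expect_equal(r$cnr[3],
               (mean(ph2$image[ph2$hot_vois[[3]]]) - mean(bgv)) / sd(bgv))
  expect_true(all(r$cnr > 0))
})
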