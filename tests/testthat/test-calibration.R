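test_that("post segmentation applies the reduction rules from known geometry", {
  ph <- generate_phantom_ct(small_phantom_spec(background_sigma = 0,
                                               psf_fwhm = 0, seed = 3))
  seg <- segment_posts(ph)
  geo <- seg$geometry
  # 15 mm post -> 13 mm x 30 mm cylinder
  i15 <- which(geo$diameter_mm == 15)[1]
  v15 <- mask_volume_ml(seg$posts[[i15]])
  # analytic 13 mm x 30 mm, one voxel-layer band (2 mm slices)
  expect_gt(v15, pi * 6.25^2 * 28 / 1000)
  expect_lt(v15, pi * 6.75^2 * 32 / 1000)
  # 2 mm post -> 1 mm diameter replacement cylinder
  i2 <- which(geo$diameter_mm == 2)[1]
  expect_equal(geo$reduced_diameter_mm[i2], 1)
  expect_lt(mask_volume_ml(seg$posts[[i2]]), pi * 1^2 * 30 / 1000)
  # 30 mm background cylinder over the reduced post length
  vb <- mask_volume_ml(seg$background)
  expect_gt(vb, pi * 15^2 * 28 / 1000)
  expect_lt(vb, pi * 15^2 * 34 / 1000)
})

test_that("calibration fitting matches closed-form least squares", {
  pts <- data.frame(concentration_mg_ml = c(0.5, 5, 25),
                    mean_hu = 10 * c(0.5, 5, 25) + 5)
  f <- fit_calibration(pts)
  expect_equal(f$m_cal, 10, tolerance = 1e-12)
  expect_equal(f$b_cal, 5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # independent closed-form OLS oracle on hand-picked points
  x <- c(1, 4, 9); y <- c(2.2, 3.9, 10.1)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  f2 <- fit_calibration(data.frame(concentration_mg_ml = x, mean_hu = y))
  expect_equal(f2$m_cal, sl, tolerance = 1e-12)
  expect_equal(f2$b_cal, ic, tolerance = 1e-12)
  # residual orthogonality at machine precision
  res <- y - (f2$b_cal + f2$m_cal * x)
  expect_lt(abs(sum(res * x)), 1e-10)
  expect_error(fit_calibration(data.frame(concentration_mg_ml = c(2, 2, 2),
                                          mean_hu = c(1, 2, 3))), "distinct")
})

test_that("the 95% detection intercept follows mu + 1.645 sigma", {
  expect_equal(compute_intercept(list(mu_bkg = 0, sigma_bkg = 1)), 1.645)
  expect_equal(compute_intercept(list(mu_bkg = 7, sigma_bkg = 0)), 7)
  set.seed(10)
  g <- make_grid(c(50, 50, 40), values = array(rnorm(1e5, 100, 4), c(50, 50, 40)))
  m <- structure_mask(array(TRUE, dim(g$values)), g)
  b <- background_stats(g, m)
  expect_equal(compute_intercept(b), 100 + 1.645 * 4, tolerance = 0.002)
  # monotone in both arguments
  expect_gt(compute_intercept(list(mu_bkg = 1, sigma_bkg = 2)),
            compute_intercept(list(mu_bkg = 1, sigma_bkg = 1)))
  expect_gt(compute_intercept(list(mu_bkg = 2, sigma_bkg = 1)),
            compute_intercept(list(mu_bkg = 1, sigma_bkg = 1)))
})

test_that("per-diameter slopes are flat without blur and biased low at 2 mm with blur", {
  ph0 <- generate_phantom_ct(small_phantom_spec(background_sigma = 0,
                                                psf_fwhm = 0, seed = 4))
  tab0 <- post_mean_table(ph0, segment_posts(ph0))
  s0 <- slope_by_diameter(tab0)
  expect_equal(s0$slope, rep(14.13, nrow(s0)), tolerance = 1e-10)

  ph1 <- generate_phantom_ct(small_phantom_spec(background_sigma = 0,
                                                psf_fwhm = 1.5, seed = 4))
  tab1 <- post_mean_table(ph1, segment_posts(ph1))
  s1 <- slope_by_diameter(tab1)
  sl2 <- s1$slope[s1$diameter_mm == 2]
  slbig <- s1$slope[s1$diameter_mm >= 9]
  expect_lt(sl2, min(slbig) - 0.1)     # partial-volume bias direction
  sl15 <- s1$slope[s1$diameter_mm == 15]
  expect_equal(sl15, 14.13, tolerance = 0.01)  # margin strips the blur layer

  one <- tab0[tab0$diameter_mm == 15, ]
  expect_equal(nrow(slope_by_diameter(one)), 1)
  expect_error(slope_by_diameter(tab0[tab0$concentration_mg_ml == 25, ]),
               "concentrations")
})

test_that("noise-free slope recovery is exact to 0.1%", {
  ph <- generate_phantom_ct(small_phantom_spec(background_sigma = 0,
                                               psf_fwhm = 0, seed = 5))
  tab <- post_mean_table(ph, segment_posts(ph))
  f <- fit_calibration(tab[tab$diameter_mm == 15, ])
  expect_lt(abs(f$m_cal - 14.13) / 14.13, 0.001)
})
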