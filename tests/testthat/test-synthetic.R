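test_that("noiseless, PSF-free phantom posts carry exactly slope*concentration", {
  sp <- small_phantom_spec(background_sigma = 0, psf_fwhm = 0,
                           true_slope = 14.13, seed = 1)
  ph <- generate_phantom_ct(sp)
  seg <- segment_posts(ph)
  tab <- post_mean_table(ph, seg)
  p15 <- tab[tab$diameter_mm == 15 & tab$concentration_mg_ml == 25, ]
  expect_equal(p15$mean_hu, 14.13 * 25, tolerance = 1e-12)  # 353.25 HU
  expect_equal(p15$sd_hu, 0)
  expect_equal(tab$mean_hu, 14.13 * tab$concentration_mg_ml, tolerance = 1e-12)
})

test_that("a zero-concentration phantom is pure background noise", {
  sp <- small_phantom_spec(concentrations = c(0, 0, 0), background_mu = 50,
                           background_sigma = 4, psf_fwhm = 0, seed = 2)
  ph <- generate_phantom_ct(sp)
  v <- as.numeric(ph$ct$values)
  expect_equal(mean(v), 50, tolerance = 0.05)
  expect_equal(sd(v), 4, tolerance = 0.05)
  expect_gt(shapiro.test(sample(v, 3000))$p.value, 1e-4)
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generate_phantom_ct(small_phantom_spec(seed = 33))
  b <- generate_phantom_ct(small_phantom_spec(seed = 33))
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$posts, b$posts)
})

test_that("phantom geometry is rejected when posts would overlap", {
  expect_error(generate_phantom_ct(
    phantom_spec(post_diameters = c(20, 22), concentrations = c(1, 2, 3),
                 post_axis_radius = 20)), "overlap")
})

test_that("Gaussian blur conserves totals away from grid edges", {
  g <- array(0, c(40, 40, 20))
  g[18:22, 18:22, 9:11] <- 7.5
  b <- y90ct:::blur_grid_values(g, c(1, 1, 2), 3)
  expect_lt(abs(sum(b) - sum(g)) / sum(g), 1e-3)
})

test_that("virtual subjects conserve activity and respond to motion", {
  vs <- generate_virtual_subject(seed = 5, liver_volume_ml = 70,
                                 ct_spacing = c(1, 1, 2))
  expect_equal(sum(vs$truth_activity$values), vs$record$A0)
  expect_true(all(vs$masks$L$voxels[vs$truth_activity$values > 0]))
  expect_true(mask_volume_ml(vs$masks$L_shell) > mask_volume_ml(vs$masks$L))
  # determinism
  vs2 <- generate_virtual_subject(seed = 5, liver_volume_ml = 70,
                                  ct_spacing = c(1, 1, 2))
  expect_identical(vs$ct$values, vs2$ct$values)
  expect_identical(vs$pet$values, vs2$pet$values)

  # respiratory smearing pushes PET activity out of the liver contour but
  # conserves the total
  still <- generate_virtual_subject(seed = 8, liver_volume_ml = 70,
                                    ct_spacing = c(1, 1, 2),
                                    resp_amplitude_mm = 0)
  moving <- generate_virtual_subject(seed = 8, liver_volume_ml = 70,
                                     ct_spacing = c(1, 1, 2),
                                     resp_amplitude_mm = 10)
  aL_still <- sum(pet_to_activity(still$pet)$values[
    resample_mask(still$masks$L, still$pet)$voxels])
  aL_moving <- sum(pet_to_activity(moving$pet)$values[
    resample_mask(moving$masks$L, moving$pet)$voxels])
  expect_lt(aL_moving, aL_still)
  expect_equal(sum(pet_to_activity(moving$pet)$values),
               sum(pet_to_activity(still$pet)$values), tolerance = 1e-6)
})

test_that("with a narrow PSF and no motion, PET recovers the administered activity", {
  vs <- generate_virtual_subject(seed = 6, liver_volume_ml = 70,
                                 ct_spacing = c(1, 1, 2),
                                 pet_fwhm_mm = 0.5, resp_amplitude_mm = 0)
  pa <- pet_to_activity(vs$pet)
  inB <- resample_mask(vs$masks$B, vs$pet)
  expect_equal(sum(pa$values[inB$voxels]) / vs$record$A0, 1, tolerance = 0.01)
})
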