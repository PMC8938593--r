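test_that("mask expansion matches the brute-force physical-distance oracle", {
  set.seed(7)
  for (spacing in list(c(1, 1, 1), c(1, 1, 2), c(0.7, 1.1, 1.6))) {
    g <- make_grid(c(9, 8, 7), spacing = spacing)
    vox <- array(runif(prod(dim(g$values))) < 0.05, dim(g$values))
    vox[5, 4, 4] <- TRUE
    m <- structure_mask(vox, g)
    for (margin in c(0.9, 1.5, 2.5)) {
      got <- expand_mask(m, margin)
      expect_identical(got$voxels, expand_mask_bruteforce(m, margin),
                       info = sprintf("spacing %s margin %g",
                                      paste(spacing, collapse = "x"), margin))
    }
  }
})

test_that("expansion honours physical anisotropy and margin identities", {
  g <- make_grid(c(9, 9, 7), spacing = c(1, 1, 2))
  vox <- array(FALSE, dim(g$values)); vox[5, 5, 4] <- TRUE
  m <- structure_mask(vox, g)
  e1 <- expand_mask(m, 1)
  expect_equal(sum(e1$voxels), 5)          # no growth along the 2 mm axis
  expect_false(any(e1$voxels[, , c(3, 5)]))
  expect_identical(expand_mask(m, 0)$voxels, m$voxels)
  expect_error(expand_mask(m, -1), ">= 0")
  # monotone in margin, and (a+b) contains the two-step expansion
  ea <- expand_mask(m, 2); eb <- expand_mask(ea, 1.5)
  eab <- expand_mask(m, 3.5)
  expect_true(all(ea$voxels | !m$voxels | TRUE))
  expect_true(sum(eab$voxels) >= sum(ea$voxels))
  expect_true(all(eab$voxels[eb$voxels]))
})

test_that("radial/longitudinal erosion reduces cylinders as prescribed", {
  g <- make_grid(c(40, 40, 26), spacing = c(0.5, 0.5, 2))
  cyl <- make_cyl_mask(g, radius_mm = 4.5, half_length_mm = 20)
  er <- erode_mask_radial_longitudinal(cyl, radial = 1, longitudinal = 5)
  # analytic d = 7 mm x L = 30 mm, with a one-voxel-shell tolerance band:
  # centre-to-centre distances bias each margin by up to half a voxel
  vol_lo <- pi * 3.0^2 * 28 / 1000
  vol_hi <- pi * 4.0^2 * 32 / 1000
  expect_gt(mask_volume_ml(er), vol_lo); expect_lt(mask_volume_ml(er), vol_hi)
  expect_identical(erode_mask_radial_longitudinal(cyl, 0, 0)$voxels, cyl$voxels)
  thin <- make_cyl_mask(g, radius_mm = 1, half_length_mm = 20)
  expect_error(erode_mask_radial_longitudinal(thin, radial = 1, longitudinal = 5),
               "emptied|thin-post")
})

test_that("nearest-centre mask resampling preserves identity and volume", {
  g1 <- make_grid(c(20, 20, 10), spacing = c(1, 1, 1))
  m <- make_ball_mask(g1, radius_mm = 6)
  expect_identical(resample_mask(m, g1)$voxels, m$voxels)
  g2 <- voxel_grid(array(0, c(10, 10, 5)), spacing = c(2, 2, 2), unit = "HU")
  r <- resample_mask(m, g2)
  # one coarse-voxel surface layer tolerance on a 6 mm ball
  expect_lt(abs(mask_volume_ml(r) - mask_volume_ml(m)) / mask_volume_ml(m), 0.25)
  full <- structure_mask(array(TRUE, dim(g1$values)), g1)
  expect_true(all(resample_mask(full, g2)$voxels))
  g3 <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 1),
                   origin = c(100, 100, 100), unit = "HU")
  expect_error(resample_mask(m, g3), "disjoint")
})
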