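stair_dose <- function() {
  g <- make_grid(c(10, 1, 1), values = array(1:10, c(10, 1, 1)), unit = "Gy")
  list(g = g, m = structure_mask(array(TRUE, c(10, 1, 1)), g))
}

test_that("dose statistics match hand computation and scale homogeneously", {
  u <- make_grid(c(4, 4, 4), values = array(10, c(4, 4, 4)), unit = "Gy")
  mu <- structure_mask(array(TRUE, c(4, 4, 4)), u)
  r <- dose_stats(u, mu)
  expect_equal(c(r$D_med, r$D_max, r$D_mu, r$sigma, r$COV, r$D70),
               c(10, 10, 10, 0, 0, 10))
  s <- stair_dose()
  r2 <- dose_stats(s$g, s$m)
  expect_equal(r2$D_mu, 5.5); expect_equal(r2$D_med, 5.5)
  expect_equal(r2$D_max, 10)
  k <- 3.7
  s$g$values <- s$g$values * k
  r3 <- dose_stats(s$g, s$m)
  expect_equal(c(r3$D_med, r3$D_mu, r3$D70), k * c(r2$D_med, r2$D_mu, r2$D70))
  expect_equal(r3$COV, r2$COV)
})

test_that("D_x is the exact order statistic and cDVH is its inverse", {
  s <- stair_dose()
  expect_equal(d_x(s$g, s$m, 70), 4)    # 7 of 10 voxels receive >= 4 Gy
  expect_equal(d_x(s$g, s$m, 100), 1)
  expect_equal(d_x(s$g, s$m, 10), 10)
  u <- make_grid(c(3, 3, 3), values = array(2.5, c(3, 3, 3)), unit = "Gy")
  mu <- structure_mask(array(TRUE, c(3, 3, 3)), u)
  expect_equal(d_x(u, mu, 37), 2.5)
  # d_x non-increasing in x; cdvh at D70 covers at least 70%
  xs <- seq(5, 100, by = 5)
  dx <- vapply(xs, function(x) d_x(s$g, s$m, x), numeric(1))
  expect_true(all(diff(dx) <= 0))
  cv <- cdvh(s$g, s$m, bins = 101)
  d70 <- d_x(s$g, s$m, 70)
  frac_at <- cv$volume_fraction[max(which(cv$dose_gy <= d70))]
  expect_gte(frac_at, 0.70)
})

test_that("the cumulative DVH is a non-increasing step survey of voxel doses", {
  u <- make_grid(c(4, 4, 4), values = array(7, c(4, 4, 4)), unit = "Gy")
  mu <- structure_mask(array(TRUE, c(4, 4, 4)), u)
  cv <- cdvh(u, mu, bins = 50)
  expect_equal(cv$volume_fraction[1], 1)
  expect_true(all(cv$volume_fraction[cv$dose_gy < 7 - 1e-9] == 1))
  two <- make_grid(c(2, 1, 1), values = array(c(0, 100), c(2, 1, 1)), unit = "Gy")
  mt <- structure_mask(array(TRUE, c(2, 1, 1)), two)
  cv2 <- cdvh(two, mt, bins = 11)
  expect_equal(cv2$volume_fraction[cv2$dose_gy > 0 & cv2$dose_gy < 100],
               rep(0.5, sum(cv2$dose_gy > 0 & cv2$dose_gy < 100)))
  set.seed(40)
  g <- make_grid(c(6, 6, 6), values = array(rexp(216, 0.1), c(6, 6, 6)),
                 unit = "Gy")
  cv3 <- cdvh(g, structure_mask(array(TRUE, c(6, 6, 6)), g))
  expect_true(all(diff(cv3$volume_fraction) <= 0))
})

test_that("LOB/LOD/MDA chain reproduces the reported detectability limits", {
  rec <- subject_record(A0 = 1e8, A_MS = 156, MS_mg = 24460)
  # sigma of the low-concentration sample chosen so LOD_conc is 0.22 mg/mL
  sigma_low <- 0.22 * 14.13 / 1.645
  det <- detectability(list(mu_bkg = 0, sigma_bkg = 2), sigma_low, 14.13, rec)
  expect_equal(det$lob_hu, 1.645 * 2)
  expect_equal(det$lod_conc, 0.22, tolerance = 1e-10)
  expect_equal(det$mda_bq_ml / 1e6, 0.84, tolerance = 0.005)  # ~0.84 MBq/mL
  det0 <- detectability(list(mu_bkg = 0, sigma_bkg = 0), 0, 14.13, rec)
  expect_equal(det0$lod_conc, 0)
  rec2 <- subject_record(A0 = 1e8, A_MS = 312, MS_mg = 24460)
  det2 <- detectability(list(mu_bkg = 0, sigma_bkg = 2), sigma_low, 14.13, rec2)
  expect_equal(det2$mda_bq_ml, 2 * det$mda_bq_ml)  # linear in A_MS
})

test_that("boundary activity fractions match the analytic shell result", {
  g <- make_grid(c(26, 26, 26), values = array(0, c(26, 26, 26)), unit = "Bq")
  ball <- make_ball_mask(g, radius_mm = 10)
  g$values[ball$voxels] <- 1
  got <- boundary_activity_fraction(g, ball, 2.4)
  expect_equal(got / 100, 1 - (7.6 / 10)^3, tolerance = 0.1)
  expect_equal(boundary_activity_fraction(g, ball, 25), 100)
  edge <- make_grid(c(8, 8, 8), values = array(0, c(8, 8, 8)), unit = "Bq")
  vox <- array(FALSE, c(8, 8, 8)); vox[3:6, 3:6, 3:6] <- TRUE
  cube <- structure_mask(vox, edge)
  edge$values[3, 4, 4] <- 5   # a voxel one spacing from the outside
  expect_equal(boundary_activity_fraction(edge, cube, 1.01), 100)
  expect_equal(boundary_activity_fraction(edge, cube, 0.5), 0)
})
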