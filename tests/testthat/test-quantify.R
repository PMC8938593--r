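make_record <- function() subject_record(A0 = 1.324e8, A_MS = 156, MS_mg = 24460)

test_that("calibration inversion clamps below the intercept", {
  g <- make_grid(c(3, 1, 1), spacing = c(0.313, 0.313, 2.0),
                 values = array(c(110, 110 + 14.13, 60), c(3, 1, 1)))
  conc <- ct_to_concentration(g, 14.13, intercept = 110)
  expect_equal(as.numeric(conc$values), c(0, 1, 0))   # at, above, below b_cal
  conc2 <- ct_to_concentration(g, 14.13, intercept = 110, clamp = FALSE)
  expect_equal(conc2$values[3, 1, 1], (60 - 110) / 14.13)  # exactly affine
  expect_error(ct_to_concentration(g, -2), "> 0")
})

test_that("concentration converts to activity through the three scalar factors", {
  g <- make_grid(c(2, 2, 2), spacing = c(0.313, 0.313, 2.0),
                 values = array(1, c(2, 2, 2)), unit = "mg/mL")
  a <- concentration_to_activity(g, make_record())
  expect_equal(a$values[1, 1, 1], 24460 * 156 * 0.313 * 0.313 * 2.0 / 1000,
               tolerance = 1e-12)                      # ~747.7 Bq
  expect_equal(a$values[1, 1, 1], 747.7, tolerance = 1e-4)
  zero <- ct_to_concentration(make_grid(c(2, 2, 2), values = array(0, c(2, 2, 2))),
                              14.13, intercept = 0)
  expect_true(all(concentration_to_activity(zero, make_record())$values == 0))
  g2 <- make_grid(c(2, 2, 2), spacing = c(0.313, 0.313, 4.0),
                  values = array(1, c(2, 2, 2)), unit = "mg/mL")
  expect_equal(concentration_to_activity(g2, make_record())$values[1, 1, 1],
               2 * a$values[1, 1, 1])                  # linear in voxel volume
})

test_that("recovery coefficients reproduce the reported per-subject arithmetic", {
  g <- make_grid(c(4, 4, 4), values = array(0, c(4, 4, 4)), unit = "Bq")
  g$values[1, 1, 1] <- 122.6e6
  m <- structure_mask(array(TRUE, c(4, 4, 4)), g)
  expect_equal(recovery_coefficient(g, m, 132.4e6), 92.6, tolerance = 0.05)
  g$values[1, 1, 1] <- 119.8e6
  expect_equal(recovery_coefficient(g, m, 171.0e6), 70.1, tolerance = 0.05)
  g$values[1, 1, 1] <- 5
  expect_equal(recovery_coefficient(g, m, 5), 100)
  expect_error(recovery_coefficient(g, m, 0), "> 0")
})

test_that("the Gaussian post-filter conserves activity and suppresses noise as the kernel norm predicts", {
  set.seed(20)
  g <- make_grid(c(40, 40, 40), spacing = c(2.039, 2.039, 2.039),
                 values = array(rnorm(64000, 100, 10), c(40, 40, 40)),
                 unit = "Bq/mL")
  expect_identical(gaussian_postfilter(g, 0)$values, g$values)
  u <- make_grid(c(20, 20, 20), spacing = c(2, 2, 2),
                 values = array(3, c(20, 20, 20)), unit = "Bq/mL")
  fu <- gaussian_postfilter(u, 4)
  expect_equal(fu$values[10, 10, 10], 3, tolerance = 1e-9)  # uniform interior

  f <- gaussian_postfilter(g, 4)
  inner <- f$values[10:30, 10:30, 10:30]
  # analytic suppression factor: the l2 norm of the discrete kernel
  sig <- 4 / (2 * sqrt(2 * log(2)))
  taps <- y90ct:::gauss_taps(sig, 2.039)
  k3 <- outer(outer(taps, taps), taps)
  expect_equal(sd(inner) / 10, sqrt(sum(k3^2)), tolerance = 0.05)
  # paper-scale sanity: ~2-3x noise suppression at 4 mm FWHM
  expect_gt(10 / sd(inner), 2)
})

test_that("activity-concentration volumes convert by voxel volume", {
  g <- make_grid(c(3, 3, 3), spacing = c(2.039, 2.039, 2.039),
                 values = array(1e6, c(3, 3, 3)), unit = "Bq/mL")
  a <- pet_to_activity(g)
  expect_equal(a$values[1, 1, 1], 8477, tolerance = 0.01)
  expect_true(all(pet_to_activity(make_grid(c(2, 2, 2),
    values = array(0, c(2, 2, 2)), unit = "Bq/mL"))$values == 0))
  expect_error(pet_to_activity(make_grid(c(2, 2, 2),
    values = array(0, c(2, 2, 2)), unit = "Bq")), "Bq/mL")
})

test_that("outside-activity ratios behave at the extremes", {
  g <- make_grid(c(10, 10, 10), values = array(0, c(10, 10, 10)), unit = "Bq")
  inner <- make_ball_mask(g, radius_mm = 2)
  outer_m <- make_ball_mask(g, radius_mm = 4.5)
  g$values[inner$voxels] <- 1
  expect_equal(activity_ratio_outside(g, inner, outer_m), 0)
  g$values[] <- 0; g$values[outer_m$voxels & !inner$voxels] <- 2
  expect_equal(activity_ratio_outside(g, inner, outer_m), 100)
  expect_error(activity_ratio_outside(g, outer_m, inner), "subset")
})

test_that("clamping never increases recovered activity", {
  set.seed(21)
  g <- make_grid(c(10, 10, 10),
                 values = array(rnorm(1000, 100, 20), c(10, 10, 10)))
  cl <- ct_to_concentration(g, 14.13, intercept = 100)
  un <- ct_to_concentration(g, 14.13, intercept = 100, clamp = FALSE)
  expect_gte(sum(cl$values), sum(un$values))  # clamp removes negatives
  expect_true(all(cl$values >= 0))
})
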