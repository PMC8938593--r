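test_that("decay arithmetic follows the 64.1 h half-life", {
  expect_equal(decayed_fraction(11.5, 2.67), 0.95, tolerance = 5e-3)
  expect_equal(decayed_fraction(0), 0)
  expect_equal(decayed_fraction(64.1 / 24), 0.5)
  expect_error(decayed_fraction(-1), ">= 0")
  k <- y90_constants()
  expect_equal(k$tau_s * k$lambda_per_s, 1)
  expect_equal(k$tau_s, 332930, tolerance = 1e-4)
})

test_that("cumulated activity is the permanent-implant integral A * tau", {
  g <- make_grid(c(2, 2, 2), values = array(1, c(2, 2, 2)), unit = "Bq")
  ca <- cumulated_activity(g)
  expect_equal(ca$values[1, 1, 1], 64.1 * 3600 / log(2), tolerance = 1e-12)
  expect_equal(ca$values[1, 1, 1], 3.3293e5, tolerance = 1e-4)
  g2 <- make_grid(c(2, 2, 2), values = array(2, c(2, 2, 2)), unit = "Bq")
  expect_equal(cumulated_activity(g2)$values, 2 * ca$values)  # linearity
  bad <- make_grid(c(2, 2, 2), values = array(-1, c(2, 2, 2)), unit = "Bq")
  expect_error(cumulated_activity(bad), "negative")
})

test_that("FFT convolution equals the brute-force triple sum to 1e-10", {
  set.seed(30)
  k <- simulate_dvk(c(2, 2, 2), histories = 1e4, nbatch = 10, rmax = 6)
  a <- voxel_grid(array(runif(9^3) * 1e5, c(9, 9, 9)), c(2, 2, 2),
                  unit = "decays")
  fast <- convolve_dose(a, k)
  slow <- convolve_dose_direct(a, k)
  expect_lt(max(abs(fast$values - slow$values)) / max(slow$values), 1e-10)
})

test_that("convolution is a sifting, linear, translation-equivariant operator", {
  set.seed(31)
  k <- simulate_dvk(c(2, 2, 2), histories = 1e4, nbatch = 10, rmax = 6)
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 3e4
  d <- convolve_dose(voxel_grid(a, c(2, 2, 2), unit = "decays"), k)
  kd <- dim(k$values); half <- (kd - 1) / 2
  sub <- d$values[6 + (-half[1]:half[1]), 6 + (-half[2]:half[2]),
                  6 + (-half[3]:half[3])]
  expect_equal(sub, 3e4 * k$values, tolerance = 1e-10)
  zero <- convolve_dose(voxel_grid(array(0, c(11, 11, 11)), c(2, 2, 2),
                                   unit = "decays"), k)
  expect_true(all(zero$values == 0))
  a2 <- array(0, c(11, 11, 11)); a2[4, 7, 5] <- 3e4
  d2 <- convolve_dose(voxel_grid(a2, c(2, 2, 2), unit = "decays"), k)
  expect_equal(d2$values[4 + 2, 7 - 1, 5 + 1], d$values[6 + 2, 6 - 1, 6 + 1],
               tolerance = 1e-10)
  expect_error(convolve_dose(voxel_grid(a, c(1, 1, 1), unit = "decays"), k),
               "spacing")
})

test_that("total absorbed energy balances cumulated decays times kernel energy", {
  set.seed(32)
  k <- simulate_dvk(c(2.5, 2.5, 2.5), histories = 2e4, nbatch = 10, rmax = 8)
  av <- array(0, c(10, 10, 10)); av[5, 5, 5] <- 5e6  # interior: kernel fits
  a <- voxel_grid(av, c(2.5, 2.5, 2.5), unit = "decays")
  d <- convolve_dose(a, k)
  mass_kg <- prod(k$spacing) * 1e-6
  lhs <- sum(d$values) * mass_kg / 1.602176634e-13
  rhs <- 5e6 * dvk_total_energy_mev(k) / 1  # interior source: exact balance
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("MIRD mean dose uses the 50 Gy kg/GBq clinical constant", {
  expect_equal(mird_mean_dose(1, 0, 1), 50)
  # one voxel at the PET minimum detectable activity of 1.0 MBq/mL
  expect_equal(mird_mean_dose(1e-3, 0, 1.03e-3), 48.5, tolerance = 0.001)
  expect_equal(round(mird_mean_dose(1e-3, 0, 1.03e-3)), 49)
  # one voxel at the CT minimum detectable activity of ~0.84 MBq/mL
  mda_ct <- 0.22 * 24460 * 156 / 1e9   # GBq/mL
  expect_equal(round(mird_mean_dose(mda_ct, 0, 1.03e-3)), 41)
  expect_equal(mird_mean_dose(1, 0.5, 1), 25)
  expect_error(mird_mean_dose(1, 0, 0), "M_kg")
})

test_that("uniform activity reproduces the physically derived MIRD constant", {
  # a region much larger than the 11 mm beta range, 1 GBq administered per kg
  set.seed(33)
  k <- simulate_dvk(c(4, 4, 4), histories = 1e5, nbatch = 20)
  const <- y90_constants()
  conc_bq_per_kg <- 1e9                      # 1 GBq per kg of tissue
  bq_per_voxel <- conc_bq_per_kg * prod(c(4, 4, 4)) * 1e-6
  n <- 19
  a <- voxel_grid(array(bq_per_voxel * const$tau_s, c(n, n, n)), c(4, 4, 4),
                  unit = "decays")
  d <- convolve_dose(a, k)
  ctr <- (n + 1) / 2
  expect_equal(d$values[ctr, ctr, ctr], mird_physical_constant(),
               tolerance = 0.02)
  expect_equal(mird_physical_constant(), 49.8, tolerance = 0.01)
  expect_lt(d$values[ctr, ctr, ctr], 50)     # Eq-5 constant bounds it above
})
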