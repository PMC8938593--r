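test_that("the beta spectrum has the right endpoint, mean and normalization", {
  sp <- build_y90_spectrum()
  expect_equal(sp$endpoint_mev, 2.28)
  expect_equal(sum(sp$density) * diff(sp$energy_mev[1:2]), 1, tolerance = 1e-6)
  expect_lt(abs(sp$mean_mev - 0.9337), 0.01)
  expect_true(all(sp$density >= 0))
  expect_gte(length(sp$energy_mev), 200)
})

test_that("the water range table reproduces the printed beta ranges", {
  tabs <- y90ct:::range_energy_tables()
  r_max <- approx(tabs$energy_mev, tabs$range_mm, 2.28)$y
  expect_equal(r_max, 11.0, tolerance = 0.03)   # CSDA range of the endpoint
})

test_that("Monte-Carlo kernels satisfy their structural invariants", {
  set.seed(101)
  k <- simulate_dvk(2.039, histories = 1e5, nbatch = 50)
  d <- dim(k$values)
  expect_true(all(d %% 2 == 1))
  ctr <- (d + 1) / 2
  expect_equal(which.max(k$values),
               (ctr[3] - 1) * d[1] * d[2] + (ctr[2] - 1) * d[1] + ctr[1])
  # zero beyond 25 mm of the origin
  cc <- lapply(1:3, function(a) (seq_len(d[a]) - ctr[a]) * k$spacing[a])
  r2 <- outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`)
  expect_true(all(k$values[r2 > 25^2] == 0))
  # energy conservation: never above the mean beta energy per decay
  expect_lte(dvk_total_energy_mev(k), build_y90_spectrum()$mean_mev)
  expect_gt(dvk_total_energy_mev(k), 0.9 * build_y90_spectrum()$mean_mev)
  # point symmetry within Monte-Carlo noise (correlation of mirrored halves)
  flipped <- k$values[d[1]:1, d[2]:1, d[3]:1]
  sel <- k$values > max(k$values) * 1e-5
  expect_gt(cor(k$values[sel], flipped[sel]), 0.99)
  # shell-averaged dose decreases with radius
  sh <- findInterval(sqrt(r2), seq(0, 12, by = 2))
  prof <- tapply(k$values[sh <= 6], sh[sh <= 6], mean)
  expect_true(all(diff(prof) < 0))
})

test_that("batch uncertainty scales like one over the square root of histories", {
  set.seed(102)
  k1 <- simulate_dvk(2.039, histories = 5e4, nbatch = 50)
  k2 <- simulate_dvk(2.039, histories = 2e5, nbatch = 50)
  ratio <- k1$central_rel_unc / k2$central_rel_unc
  expect_gt(ratio, 1.3); expect_lt(ratio, 3)
})

test_that("the straight-line MC agrees with the deterministic DPK oracle", {
  set.seed(103)
  k <- simulate_dvk(2.039, histories = 2e5, scatter = FALSE, deltas = FALSE)
  o <- dvk_from_dpk(y90_dpk(), 2.039, dims = c(9, 9, 9))
  cmc <- dvk_central(k); cdet <- dvk_central(o)
  expect_lt(abs(cmc - cdet), 3 * k$central_rel_unc * cmc)
  # symmetry of the deterministic kernel is exact by construction
  expect_lt(max(abs(o$values - o$values[9:1, 9:1, 9:1])) / max(o$values), 1e-12)
})

test_that("the DPK oracle conserves the radial kernel's total energy", {
  dpk <- y90_dpk()
  o <- dvk_from_dpk(dpk, c(2.5, 2.5, 2.5))
  e_dpk <- sum(dpk$energy_mev_per_mm) * diff(dpk$r_mm[1:2])
  expect_equal(dvk_total_energy_mev(o), e_dpk, tolerance = 0.02)
  expect_error(dvk_from_dpk(dpk[dpk$r_mm < 8, ], 2.039), "truncated")
})

test_that("kernels round-trip through NIfTI plus sidecar", {
  set.seed(104)
  k <- simulate_dvk(c(3, 3, 3), histories = 1e4, nbatch = 10, rmax = 10)
  f <- file.path(tempdir(), "k.nii.gz")
  write_kernel(k, f)
  r <- read_kernel(f)
  expect_equal(r$values, k$values, tolerance = 1e-12)
  expect_equal(r$histories, k$histories)
})
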