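# y90ct

CT-based voxel dosimetry for yttrium-90 radioembolization with radiopaque
microspheres.

Post-treatment dosimetry in ⁹⁰Y radioembolization is usually built on ⁹⁰Y
PET or bremsstrahlung SPECT, whose 5–10+ mm resolution blurs the highly
heterogeneous microsphere deposition and the dose metrics derived from it.
Radiopaque glass microspheres make the deposition visible directly in CT
at sub-millimetre resolution. `y90ct` implements the complete
quantification chain for that approach, for medical physicists and
imaging scientists who want to compute, test, or compare CT- and
PET-based ⁹⁰Y dose distributions:

* **Calibration** — a 27-post phantom relates Hounsfield units to
  microsphere concentration, `HU = m_cal·MS_con + b_cal`; the slope comes
  from OLS on the 15 mm posts, the intercept per subject from the
  one-sided 95% point of the liver background,
  `b_cal = μ_bkg + 1.645·σ_bkg`.
* **Quantification** — voxel activity
  `A_CT = MS_con · MS_mg · A_MS · V_CT` (spheres/mg, Bq/sphere, voxel
  volume), recovery coefficients `RC = 100·ΣA/A₀`, PET post-filtering and
  activity-partition ratios.
* **Dosimetry** — cumulated activity `Ã = τ·A` (permanent implant,
  τ = 64.1 h/ln 2), dose by zero-padded FFT convolution with a
  Monte-Carlo ⁹⁰Y dose-voxel kernel (condensed-history beta transport
  with Møller delta rays in a voxelized water sphere), and the MIRD
  mono-compartment reference `D = A₀·50·(1−R)/M`.
* **Metrics & agreement** — D_med/D_max/D_μ/σ/COV, cumulative DVHs and
  D70, LOB/LOD/MDA detectability limits, boundary activity fractions,
  linear regression with 95% CIs, Bland–Altman limits of agreement, and
  one-way ANOVA.
* **Synthetic data** — generators for the calibration phantom and whole
  virtual subjects (ground-truth activity plus simulated CT and PET),
  so the entire pipeline runs and is tested without any image downloads.

## Worked example

```r
library(y90ct)

# 1. calibration: synthetic 27-post phantom at the scan geometry
ph    <- generate_phantom_ct(phantom_spec(seed = 1))
tab   <- post_mean_table(ph, segment_posts(ph))
curve <- fit_calibration(tab[tab$diameter_mm == 15, ])
curve
#> <CalibrationCurve> m_cal = 14.125 HU/(mg/mL) [95% CI 14.108, 14.142], b = -0.03 HU, r^2 = 1.00000

# 2. a virtual subject with known ground truth (coarsened grid for speed)
vs  <- generate_virtual_subject(seed = 1, ct_spacing = c(1, 1, 2))
bkg <- background_stats(vs$ct, vs$masks$L_bkg)
conc <- ct_to_concentration(vs$ct, curve,
                            intercept = compute_intercept(bkg),
                            mask = vs$masks$L)
act  <- concentration_to_activity(conc, vs$record)
recovery_coefficient(act, vs$masks$L, vs$record)
#> [1] 55.3

# 3. dose: kernel for this grid, then convolution dosimetry
set.seed(1)
k  <- simulate_dvk(c(1, 1, 2), histories = 2e5)
dd <- convolve_dose(cumulated_activity(act), k)
dose_stats(dd, vs$masks$L)
#> <DoseReport> D_med 2.24, D_max 4306.67, D_mu 46.70, sigma 167.58, COV 3.59, D70 0.51 Gy (39520 voxels)
```

The fitted slope recovers the generator's ground truth (14.13 HU per
mg/mL) with r² ≈ 1. The recovery coefficient of 55% on this noisy subject
is the detectability limit at work: the generator spreads most of the
activity as a diffuse low-concentration component whose enhancement falls
below the 95% detection intercept, the same mechanism offered for the
low-recovery animals in in-vivo data (a noiseless subject closes the loop
at RC ≈ 100%, which the test suite asserts). The dose report shows the
hallmark of CT-based dosimetry: a highly heterogeneous distribution
(COV ≈ 3.6, maxima in the kGy range along embolized vessels) whose mean
sits far below the MIRD uniform-model dose for the same administration.

`run_full_study()` chains all stages — phantom, calibration, subjects,
kernels, CT and PET dose distributions, metrics tables, and the
cross-modality regression / Bland–Altman / ANOVA summary — from a single
seeded configuration.

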