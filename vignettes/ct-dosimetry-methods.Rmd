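---
title: "Methods: CT-based voxel dosimetry for Y-90 radioembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT-based voxel dosimetry for Y-90 radioembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y90ct)
```

## The problem

Yttrium-90 radioembolization delivers beta-emitting microspheres into the
hepatic arterial tree. Because ⁹⁰Y is a pure beta emitter (endpoint
2.28 MeV, mean 0.93 MeV, maximum range in water ~11 mm), the absorbed-dose
distribution is set by the microsphere spatial distribution at the
millimetre scale — far below the 5–10 mm resolution of post-treatment ⁹⁰Y
PET. Radiopaque microspheres make the deposition directly visible in CT,
and `y90ct` implements the full quantification chain for that idea:

1. **Calibration** — a multi-post phantom relates Hounsfield units to
   microsphere concentration, `HU = m_cal · MS_con + b_cal`.
2. **Quantification** — CT volumes are inverted to concentration and
   scaled to a voxelized ⁹⁰Y activity `A_CT = MS_con · MS_mg · A_MS · V`.
3. **Dosimetry** — the cumulated activity `Ã = τ·A` of the permanent
   implant is convolved with a Monte-Carlo dose-voxel kernel (DVK);
   a MIRD mono-compartment dose `A₀·50·(1−R)/M` serves as reference.
4. **Metrics and agreement** — per-structure dose statistics, cumulative
   DVHs and D70, detectability limits, and CT-vs-PET regression,
   Bland–Altman and ANOVA comparisons.

Because no image data ship with the package, a synthetic module generates
the calibration phantom and whole virtual subjects with known ground
truth; every downstream stage is exercised against that truth.

## Calibration model

The phantom holds 27 cylindrical posts (diameters 2–9 mm and 15 mm, three
concentrations 0.5/5.0/25.0 mg/mL, length 40 mm) on a 100 mm ring in a
uniform resin background, imaged on a 0.313 × 0.313 × 2.0 mm grid.
`segment_posts()` reproduces the analysis rules: posts are reduced by a
1 mm radial and 5 mm longitudinal margin; the 2 mm posts, which a 1 mm
radial margin would erase, are replaced by a centred 1 mm cylinder; a
30 mm central cylinder samples the background. The default curve is fitted
by unweighted OLS to the 15 mm posts only — the diameter-resolved fit
(`slope_by_diameter()`) shows the slope is diameter-independent above
2 mm, while the 2 mm post is biased low by partial-volume averaging.

The intercept is *not* taken from the fit. Each subject gets
`b_cal = μ_bkg + 1.645·σ_bkg` from a non-embolized liver region
(`compute_intercept()`): the one-sided 95% point of the background HU
distribution, so that voxels above `b_cal` contain microspheres with 95%
confidence. Inversion clamps concentrations to zero below `b_cal`
(`ct_to_concentration(clamp = TRUE)`) — by construction those voxels are
not credibly embolized, and the clamp keeps activity sums stable against
noise. The clamp is toggleable for sensitivity studies.

**Phantom mass integration is different.** Recovering the *mass* in a
contour (the expanding-shell analysis around the 2 mm post) integrates
`(HU − b_cal)/m_cal` over a region much larger than the post. Using the
95%-guard intercept there subtracts `1.645·σ` from every voxel and biases
the mass low by ~5%; zero-mean noise cancels in a sum without any guard.
The phantom analyses therefore use the background-subtracted (ΔHU) mode:
`b_cal = μ_bkg`, no clamp. With that convention the 2 mm post mass is
recovered well within 3% through a 2 mm expanded contour.

## Dose-voxel kernels

`simulate_dvk()` computes absorbed dose per decay on a voxel lattice from
a reduced condensed-history Monte Carlo: ⁹⁰Y decays uniform in the origin
voxel of a 25 mm voxelized water sphere, electron energies sampled from a
Fermi-theory spectrum (allowed shape with the relativistic Coulomb
function; mean 0.9286 MeV, within 1% of the tabulated 0.93 MeV),
continuous slowing down on ESTAR water range–energy tables, Highland
multiple scattering per step (step ≤ half the smallest voxel dimension,
≤ 1 mm), explicit Møller knock-on electrons above 10 keV transported like
primaries (softer knock-ons have micron ranges and stay in the restricted
continuous loss), a 1 keV transport cut-off, and no bremsstrahlung photon
transport (≤1% of the energy budget in water). Voxels whose centre lies
beyond 25 mm are zeroed so the kernel is spherically bounded; the lattice
is odd-dimensioned with the source voxel at the exact centre. Central-voxel
uncertainty comes from the variance across 100 history batches.

Two independent routes guard the implementation. `y90_dpk()` computes the
straight-ahead CSDA radial dose-point kernel in closed form from the same
spectrum and range tables, and `dvk_from_dpk()` integrates it over
source–target voxel pairs by deterministic quadrature (tensor-product
Gauss–Legendre under the triangular displacement density; the singular
self-dose voxel uses the exact distance-density of two uniform points).
Run with `scatter = FALSE, deltas = FALSE`, the Monte Carlo agrees with
this deterministic route to within its statistical uncertainty, which
validates the voxelization, source sampling and scoring independently of
the transport refinements.

**Bias budget and a known discrepancy.** For the 2.039 mm isotropic
(PET-grid) voxel the model reproduces the reference central-voxel dose to
within ~8% (3.27×10⁻⁹ vs 3.55×10⁻⁹ Gy/history), inside the ~10% we budget
for the reduced physics (no delta rays below 10 keV transported laterally
within a step, Highland small-angle approximation, free-electron Møller
terms). For the thin CT voxel (0.313 × 0.313 × 2.0 mm) our model gives
3.20×10⁻⁸ Gy/history where 2.21×10⁻⁸ has been reported. We believe the
printed value cannot follow from the stated protocol: the reported dose
implies an effective local energy deposition of ~1.3 MeV/cm along the
track, below the restricted collision stopping power of water with *all*
knock-ons above 10 keV removed (~1.45 MeV/cm at 1 MeV) — and sub-10-keV
knock-ons have micron ranges, so their energy cannot leave a 0.3 mm
voxel. Both of our independent routes agree with each other to <0.5% on
this geometry. We report our computed value and flag the difference
rather than tuning toward the reported number.

## Convolution dosimetry

Microspheres are permanent implants, so `Ã = A·τ` with
τ = 64.1 h/ln 2 ≈ 3.33×10⁵ s (`cumulated_activity()`); no multi-time-point
imaging enters. `convolve_dose()` evaluates the dose sum with a zero-padded
FFT — *linear*, not circular, convolution, because embolized livers sit
near grid edges and wrap-around would alias dose across the volume. The
FFT path is asserted against a brute-force triple sum to 10⁻¹⁰ relative
accuracy on small grids. Dose is computed in water everywhere (the kernel
medium); no density scaling is applied. CT-grid doses use the CT-spacing
kernel and PET-grid doses the PET-spacing kernel; masks, not doses, are
resampled across grids (nearest-centre assignment, `resample_mask()` —
the attribution of PET voxels to CT-drawn contours is a convention we fix
because none is standard).

As a consistency check, filling a region much larger than the beta range
with uniform cumulated activity drives the central convolved dose to
τ·Ē·1.602×10⁻¹³·10⁹ ≈ 49.8 Gy per GBq/kg, the physical counterpart of the
clinical MIRD constant 50 (kept literally in `mird_mean_dose()`).

## The synthetic data

`generate_phantom_ct()` rasterizes the phantom with partial-volume
(coverage-weighted) post edges, applies a Gaussian PSF (default 1 mm
FWHM), and adds Gaussian noise (default 4 HU) — the noise level and grid
of the calibration scan it emulates. Fixed seeds give bit-identical
volumes.

`generate_virtual_subject()` builds an ellipsoidal liver (default 79 mL;
study range 65–97 mL) and deposits the administered activity (default
144.2 MBq, range 128–171) along a random binary tree of segments with
branch-wise lognormal concentration multipliers, plus a diffuse perfusion
component (the same arterial pattern smoothed to lobar scale) holding 65%
of the activity. The pure tree alone is far too sparse — its dose COV is
6–10 — while real livers show liver-dose COV near 2; the diffuse fraction
is the generator's one calibrated parameter, set so the CT-grid liver
dose COV lands in the reported 1.6–2.6 band. The CT chain applies the
affine forward model (slope 14.13 HU per mg/mL) on liver background
69–110 HU, an optional contrast-nonuniformity gradient (default 5 HU), a
1 mm PSF and 3–6 HU noise. The PET chain aggregates the truth onto a
2.039 mm grid, blurs by the system PSF (default 7 mm FWHM within the
reported 5–10 mm), and averages over a uniform cranial–caudal respiratory
displacement (default 10 mm full width, the maximum observed); optional
noise with positivity truncation mimics the low-count reconstruction
bias, off by default. Bookkeeping is exact: the truth activity sums to
A₀ by construction, and blur/smearing operators conserve totals up to
boundary truncation.

What the generator does *not* emulate: real hepatic anatomy or tumours,
beam hardening and CT artifacts, PET count statistics and scatter/randoms
structure, and co-registration error between modalities. Passing tests
demonstrate the correctness of the quantification chain given the stated
forward models, not clinical performance on real scans.

## Metrics conventions

* Voxel populations use the population standard deviation (÷n);
  across-subject summaries use the sample SD (÷(n−1)).
* `d_x()` is the exact order statistic — the ⌈x%·n⌉-th voxel dose from the
  top, no interpolation — so D70 is reproducible and conservative;
  `cdvh()` evaluated at D70 always covers ≥70% of the volume.
* Boundary activity fractions measure the distance of in-mask voxel
  centres to the nearest *outside voxel* via an exact anisotropic
  Euclidean distance transform in millimetres; margins are always
  physical, never voxel counts (grids are anisotropic).
* Detectability follows the one-sided 95% chain
  LOB = μ + 1.645σ (μ = 0 in ΔHU mode), LOD_HU = LOB + 1.645σ₀.₅,
  LOD_conc = (LOD_HU − b_cal)/m_cal with b_cal equal to the LOB of the
  same background, MDA = LOD_conc·MS_mg·A_MS.
* Cross-modality pairing is fixed: CT mean dose over L against PET mean
  dose over L_shell (L expanded isotropically by 1 cm), the convention
  that compensates PET resolution and respiratory smearing. The
  Bland–Altman "95% intervals" are limits of agreement, bias ± 1.96·SD.

## Numerical choices

* Voxel centres sit at `origin + (i + 0.5)·spacing`; NIfTI stores the
  first voxel-centre position and the conversion is handled in I/O.
* Distance transforms use the exact Felzenszwalb parabolic-envelope
  algorithm with physical spacings (a large finite sentinel replaces
  infinity to keep the parabola intersections NaN-free).
* Morphological margins compare centre-to-centre distances; erosion of a
  d-mm cylinder is therefore accurate to half a voxel per surface, and
  tests assert analytic volumes within a one-voxel shell.
* FFT sizes are padded to highly composite lengths (`nextn`); tiny
  negative round-off values in the inverse transform are clamped to zero.
* All randomness flows through R's RNG (`set.seed()`), including the C++
  transport code, so a single seed reproduces phantoms, subjects and
  kernels bit-identically.

## Problem sizes used in the shipped analyses

The package's own studies run at the acquisition geometry where results
depend on it (the full 27-post phantom on the 0.313 × 0.313 × 2.0 mm
grid; kernels at 10⁶ histories, ~0.1% central-voxel uncertainty) and on
coarsened grids (~1–1.2 mm in-plane, 5×10⁴-history kernels) for
virtual-subject pipeline demonstrations, where the tested properties —
closure, conservation, COV ordering, determinism — are grid-independent.

## Known limitations

* Kernel physics is a reduced model of a general-purpose Monte Carlo
  code: no bremsstrahlung photons, no sub-10-keV delta transport, Møller
  scattering off free electrons, Gaussian (Highland) multiple scattering.
  The stated bias budget is ~10% for millimetre-scale voxels; sub-voxel
  dose gradients inside 0.3 mm voxels are at the model's edge.
* The ΔHU calibration variant is exercised only on synthetic data where
  registration is exact; real pre/post registration is out of scope.
* No partial-volume correction beyond the clamp; no tissue-density
  scaling of dose; no DICOM/RTSTRUCT I/O (NIfTI and MetaImage only).
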