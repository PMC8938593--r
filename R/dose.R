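#' Y-90 decay constants
#'
#' Half-life 64.1 h; `tau = half_life / ln 2` is the mean lifetime
#' (~332,930 s), the full decay integral per unit initial activity of a
#' permanent implant.
#'
#' @param half_life_h half-life in hours.
#' @return Object of class `DecayConstants`: `half_life_h`, `lambda_per_s`,
#'   `tau_s`.
#' @export
y90_constants <- function(half_life_h = 64.1) {
  stopifnot(half_life_h > 0)
  tau <- half_life_h * 3600 / log(2)
  structure(list(half_life_h = half_life_h, lambda_per_s = 1 / tau,
                 tau_s = tau),
            class = "DecayConstants")
}

#' Fraction of activity decayed after a time
#'
#' `1 - 2^(-t / half_life)`; about 95% of Y-90 has decayed after 11.5 days.
#'
#' @param t_days elapsed time in days (>= 0).
#' @param half_life_days half-life in days.
#' @return Decayed fraction in `[0, 1)`.
#' @export
decayed_fraction <- function(t_days, half_life_days = 64.1 / 24) {
  if (any(t_days < 0)) stop("`t_days` must be >= 0")
  1 - 2^(-t_days / half_life_days)
}

#' Cumulated activity of a permanent implant
#'
#' Microspheres are permanent implants, so the time-integrated activity is
#' simply `A * tau` per voxel: no multi-time-point imaging is required.
#'
#' @param activity Bq [voxel_grid()] (non-negative).
#' @param constants a [y90_constants()].
#' @return A [voxel_grid()] in decays.
#' @export
cumulated_activity <- function(activity, constants = y90_constants()) {
  stopifnot(inherits(activity, "VoxelGrid"))
  if (activity$unit != "Bq") stop("`activity` must carry the Bq unit tag")
  if (any(activity$values < 0))
    stop("negative activity voxels: upstream conversion bug")
  voxel_grid(activity$values * constants$tau_s, activity$spacing,
             activity$origin, unit = "decays")
}

#' Convolution dosimetry with a dose-voxel kernel
#'
#' Linear (zero-padded, non-circular) FFT convolution of a cumulated
#' activity distribution with a spatially invariant kernel centred on its
#' source voxel. Zero padding keeps dose from wrapping across the grid —
#' embolized livers sit near grid edges. The output grid geometry equals
#' the input's.
#'
#' @param cumulated decays [voxel_grid()].
#' @param kernel a `DoseVoxelKernel` with the same voxel spacing.
#' @return A Gy [voxel_grid()].
#' @export
convolve_dose <- function(cumulated, kernel) {
  stopifnot(inherits(cumulated, "VoxelGrid"),
            inherits(kernel, "DoseVoxelKernel"))
  if (cumulated$unit != "decays")
    stop("`cumulated` must carry the decays unit tag")
  if (any(abs(cumulated$spacing - kernel$spacing) > 1e-6))
    stop("kernel and grid voxel spacings differ")
  nd <- dim(cumulated$values)
  nk <- dim(kernel$values)
  half <- (nk - 1L) %/% 2L
  np <- vapply(nd + nk - 1L, function(n) stats::nextn(n, c(2, 3, 5)), integer(1))
  pa <- array(0, np); pa[1:nd[1], 1:nd[2], 1:nd[3]] <- cumulated$values
  pk <- array(0, np); pk[1:nk[1], 1:nk[2], 1:nk[3]] <- kernel$values
  conv <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / prod(np)
  out <- conv[half[1] + 1:nd[1], half[2] + 1:nd[2], half[3] + 1:nd[3]]
  out[abs(out) < .Machine$double.eps * max(abs(out))] <- 0
  out[out < 0] <- 0  # FFT round-off can leave tiny negatives
  voxel_grid(out, cumulated$spacing, cumulated$origin, unit = "Gy")
}

#' Brute-force convolution (reference implementation)
#'
#' Direct triple-sum evaluation of the convolution on small grids; the
#' oracle against which the FFT path is checked.
#'
#' @inheritParams convolve_dose
#' @return A Gy [voxel_grid()].
#' @export
convolve_dose_direct <- function(cumulated, kernel) {
  stopifnot(inherits(cumulated, "VoxelGrid"),
            inherits(kernel, "DoseVoxelKernel"))
  nd <- dim(cumulated$values)
  nk <- dim(kernel$values)
  half <- (nk - 1L) %/% 2L
  a <- cumulated$values
  k <- kernel$values
  out <- array(0, nd)
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    s <- 0
    for (xp in 1:nd[1]) for (yp in 1:nd[2]) for (zp in 1:nd[3]) {
      i <- x - xp + half[1] + 1L
      j <- y - yp + half[2] + 1L
      l <- z - zp + half[3] + 1L
      if (i >= 1L && i <= nk[1] && j >= 1L && j <= nk[2] &&
          l >= 1L && l <= nk[3])
        s <- s + a[xp, yp, zp] * k[i, j, l]
    }
    out[x, y, z] <- s
  }
  voxel_grid(out, cumulated$spacing, cumulated$origin, unit = "Gy")
}

#' MIRD mono-compartment mean dose
#'
#' `D = A0 * 50 * (1 - R) / M` with `A0` in GBq, `M` in kg and `R` the
#' fractional residual activity — the uniform-distribution reference model
#' used for treatment planning. The clinical constant 50 Gy kg/GBq is kept
#' literally; the physically derived value `tau * E_mean * 1.602e-13 * 1e9`
#' is ~49.8 and is available via [mird_physical_constant()].
#'
#' @param A0_gbq administered activity in GBq.
#' @param R fractional residual activity in `[0, 1)`.
#' @param M_kg target mass in kg (> 0).
#' @return Mean absorbed dose in Gy.
#' @export
mird_mean_dose <- function(A0_gbq, R = 0, M_kg) {
  stopifnot(M_kg > 0, R >= 0, R < 1)
  A0_gbq * 50 * (1 - R) / M_kg
}

#' Physically derived MIRD coefficient
#'
#' Gy kg per GBq of a permanent Y-90 implant: mean lifetime times mean
#' beta energy in joules times 1e9 decays per second per GBq.
#'
#' @param constants a [y90_constants()].
#' @param mean_energy_mev mean beta energy in MeV.
#' @return Coefficient in Gy kg/GBq (~49.8).
#' @export
mird_physical_constant <- function(constants = y90_constants(),
                                   mean_energy_mev = build_y90_spectrum()$mean_mev) {
  constants$tau_s * mean_energy_mev * 1.602176634e-13 * 1e9
}
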