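new_dvk <- function(values, spacing, histories, central_rel_unc,
                    method) {
  structure(list(values = values, spacing = spacing,
                 histories = histories,
                 central_rel_unc = central_rel_unc,
                 method = method, unit = "Gy/history"),
            class = "DoseVoxelKernel")
}

#' @export
print.DoseVoxelKernel <- function(x, ...) {
  ci <- (dim(x$values) + 1) / 2
  cat(sprintf("<DoseVoxelKernel %s> %s voxels @ %s mm, central %.4g Gy/history%s\n",
              x$method, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$values[ci[1], ci[2], ci[3]],
              if (is.finite(x$central_rel_unc))
                sprintf(" (rel. unc. %.2g%%)", 100 * x$central_rel_unc) else ""))
  invisible(x)
}

#' Central (source-voxel) value of a dose-voxel kernel
#' @param kernel a `DoseVoxelKernel`.
#' @return Central-voxel absorbed dose in Gy per history.
#' @export
dvk_central <- function(kernel) {
  ci <- (dim(kernel$values) + 1) / 2
  kernel$values[ci[1], ci[2], ci[3]]
}

dvk_lattice_dim <- function(spacing, rmax) {
  2L * as.integer(ceiling(rmax / spacing)) + 1L
}

mask_beyond_rmax <- function(values, spacing, rmax) {
  d <- dim(values)
  ctr <- (d + 1) / 2
  cx <- (seq_len(d[1]) - ctr[1]) * spacing[1]
  cy <- (seq_len(d[2]) - ctr[2]) * spacing[2]
  cz <- (seq_len(d[3]) - ctr[3]) * spacing[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  values[r2 > rmax^2] <- 0
  values
}

#' Monte-Carlo Y-90 dose-voxel kernel
#'
#' Simulates beta decays uniformly distributed in the origin voxel of a
#' voxelized water sphere and scores absorbed dose per voxel. Transport is
#' a reduced condensed-history model: electron energies sampled from the
#' Y-90 spectrum, restricted continuous-slowing-down energy loss from
#' water range-energy tables, explicit Moller knock-on (delta-ray)
#' production above 10 keV with secondaries transported like primaries,
#' Highland multiple scattering per step, and no bremsstrahlung photon
#' transport (sub-percent of the energy budget in water). Voxels whose
#' centre lies beyond `rmax` of the origin are zeroed so the kernel is
#' spherically bounded. The lattice is odd along every axis with the
#' source voxel at the exact centre.
#'
#' Randomness is drawn from R's RNG stream, so `set.seed()` makes the
#' kernel reproducible. Central-voxel uncertainty is estimated from the
#' variance across history batches.
#'
#' @param spacing voxel spacing in mm (length 3, or a scalar for isotropic
#'   voxels).
#' @param histories number of decays (>= 1e4).
#' @param scatter apply Highland multiple scattering (default `TRUE`).
#' @param deltas produce and transport knock-on electrons above `w_min`
#'   (default `TRUE`). With `scatter = FALSE, deltas = FALSE` the model is
#'   straight-ahead unrestricted CSDA, shared with [y90_dpk()].
#' @param w_min delta-ray production threshold in MeV; softer knock-ons
#'   stay in the continuous loss (their range is microns).
#' @param nbatch number of batches for the variance estimate.
#' @param rmax water-sphere radius in mm.
#' @param step_max_mm optional cap on the condensed-history step length
#'   (the default is half the smallest voxel dimension, at most 1 mm).
#' @param spectrum a [build_y90_spectrum()].
#' @return A `DoseVoxelKernel` (values in Gy per history).
#' @export
simulate_dvk <- function(spacing, histories = 1e6, scatter = TRUE,
                         deltas = TRUE, w_min = 0.01,
                         nbatch = 100, rmax = 25, step_max_mm = 1,
                         spectrum = build_y90_spectrum()) {
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive")
  histories <- as.integer(histories)
  if (histories < 1e4) stop("`histories` must be >= 1e4")
  dims <- vapply(spacing, dvk_lattice_dim, integer(1), rmax = rmax)
  icdf <- spectrum_inverse_cdf(spectrum)
  if (deltas) {
    mt <- moller_tables(w_min)
    e_tab <- mt$energy_mev; r_tab <- mt$range_res_mm; s_tab <- mt$sigma_per_mm
  } else {
    tabs <- range_energy_tables()
    e_tab <- tabs$energy_mev; r_tab <- tabs$range_mm
    s_tab <- numeric(length(e_tab))
  }
  res <- dvk_transport(dims, spacing, histories, as.integer(nbatch),
                       e_tab, r_tab, s_tab, icdf,
                       scatter, deltas, w_min, rmax, step_max_mm)
  mev_to_j <- 1.602176634e-13
  mass_kg <- prod(spacing) * 1e-6  # water, 1 g/cm^3
  vals <- array(res$energy, dims) * mev_to_j / mass_kg / res$histories
  vals <- mask_beyond_rmax(vals, spacing, rmax)
  cb <- res$central_batch
  rel <- if (mean(cb) > 0) sd(cb) / sqrt(length(cb)) / mean(cb) else NA_real_
  k <- new_dvk(vals, spacing, res$histories, rel, method = "monte-carlo")
  k$total_energy_mev_per_history <- sum(res$energy) / res$histories
  k
}

#' Dose-voxel kernel by deterministic integration of a radial kernel
#'
#' Integrates a radial dose-point kernel over source-voxel/target-voxel
#' point pairs. The source-to-target displacement within a voxel pair has
#' a per-axis triangular distribution of half-width one voxel; off-centre
#' voxels use tensor-product Gauss-Legendre quadrature under that weight,
#' while the singular self-dose voxel integrates the kernel against the
#' exact distance density (spherical average of the triangular product via
#' a Fibonacci direction set). Point symmetry holds by construction.
#'
#' @param dpk data frame from [y90_dpk()] (`r_mm`, `dose_gy_per_decay`);
#'   must extend past the endpoint CSDA range (~11 mm).
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param rmax masking radius in mm.
#' @param dims optional odd lattice dimensions (defaults to covering
#'   `rmax`); smaller lattices are useful for quick cross-checks.
#' @param n_quad Gauss-Legendre nodes per axis for off-centre voxels.
#' @return A `DoseVoxelKernel` (values in Gy per history).
#' @export
dvk_from_dpk <- function(dpk, spacing, rmax = 25, dims = NULL, n_quad = 4) {
  spacing <- rep_len(as.numeric(spacing), 3)
  if (max(dpk$r_mm) < 11)
    stop("dose-point kernel table truncated before the CSDA range")
  if (is.null(dims)) dims <- vapply(spacing, dvk_lattice_dim, integer(1), rmax = rmax)
  dims <- as.integer(dims)
  if (any(dims %% 2L == 0L)) stop("`dims` must be odd")
  dose_fun <- approxfun(dpk$r_mm, dpk$dose_gy_per_decay, yleft = NA, yright = 0)
  r_support <- max(dpk$r_mm)

  quad_pts <- function(nq) {
    gl <- gauss_legendre(nq)
    nd <- lapply(spacing, function(h) {
      x <- gl$x * h
      w <- gl$w * (1 - abs(x) / h)
      list(x = x, w = w / sum(w))
    })
    g3 <- expand.grid(i = seq_len(nq), j = seq_len(nq), k = seq_len(nq))
    list(x = nd[[1]]$x[g3$i], y = nd[[2]]$x[g3$j], z = nd[[3]]$x[g3$k],
         w = nd[[1]]$w[g3$i] * nd[[2]]$w[g3$j] * nd[[3]]$w[g3$k])
  }
  qfar <- quad_pts(n_quad)
  qnear <- quad_pts(max(12L, n_quad))  # near-source windows see the 1/r^2 spike

  ctr <- (dims + 1) / 2
  offx <- (seq_len(dims[1]) - ctr[1]) * spacing[1]
  offy <- (seq_len(dims[2]) - ctr[2]) * spacing[2]
  offz <- (seq_len(dims[3]) - ctr[3]) * spacing[3]
  vals <- array(0, dims)
  for (k in seq_len(dims[3])) {
    oz <- offz[k]
    sl <- matrix(0, dims[1], dims[2])
    for (j in seq_len(dims[2])) {
      oy <- offy[j]
      # skip voxels fully beyond the kernel support
      dmin <- sqrt(pmax(abs(offx) - spacing[1], 0)^2 +
                   max(abs(oy) - spacing[2], 0)^2 +
                   max(abs(oz) - spacing[3], 0)^2)
      act <- which(dmin <= r_support)
      if (!length(act)) next
      near_j <- abs(oy) <= 1.5 * spacing[2] && abs(oz) <= 1.5 * spacing[3]
      for (i in act) {
        q <- if (near_j && abs(offx[i]) <= 1.5 * spacing[1]) qnear else qfar
        r <- sqrt((offx[i] + q$x)^2 + (oy + q$y)^2 + (oz + q$z)^2)
        d <- dose_fun(r)
        if (anyNA(d)) d[is.na(d)] <- dose_fun(min(dpk$r_mm))
        sl[i, j] <- sum(q$w * d)
      }
    }
    vals[, , k] <- sl
  }
  # exact self-dose: integrate the kernel against the |displacement| pdf
  vals[ctr[1], ctr[2], ctr[3]] <- dvk_self_dose(dpk, spacing)
  vals <- mask_beyond_rmax(vals, spacing, rmax)
  new_dvk(vals, spacing, NA_integer_, NA_real_, method = "dpk-integration")
}

# Self-dose of the source voxel: E[DPK(|d|)] where d is the difference of
# two uniform points in the voxel (triangular product density). The pdf of
# |d| is built by spherically averaging the product density over a
# Fibonacci direction set, then the radial integral is taken on the DPK's
# own grid.
dvk_self_dose <- function(dpk, spacing, n_dir = 2000) {
  i <- seq_len(n_dir) - 0.5
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  cz <- 1 - 2 * i / n_dir
  sz <- sqrt(pmax(1 - cz^2, 0))
  dirs <- cbind(sz * cos(phi), sz * sin(phi), cz)
  dr <- diff(dpk$r_mm[1:2])
  r <- dpk$r_mm[dpk$r_mm <= sqrt(sum(spacing^2))]
  tri <- function(x, h) ifelse(abs(x) < h, (1 - abs(x) / h) / h, 0)
  g <- vapply(r, function(s) {
    p <- tri(s * dirs[, 1], spacing[1]) * tri(s * dirs[, 2], spacing[2]) *
      tri(s * dirs[, 3], spacing[3])
    4 * pi * s^2 * mean(p)
  }, numeric(1))
  # g is the pdf of |d|; normalize residual quadrature error
  g <- g / (sum(g) * dr)
  sum(g * dpk$dose_gy_per_decay[seq_along(g)]) * dr
}

gauss_legendre <- function(n) {
  # Golub-Welsch via the symmetric Jacobi matrix
  if (n == 1) return(list(x = 0, w = 2))
  b <- (1:(n - 1)) / sqrt(4 * (1:(n - 1))^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- 2 * ev$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Total absorbed energy of a kernel in MeV per history
#'
#' `sum(values * voxel water mass)`, converted to MeV; bounded above by the
#' mean beta energy per decay.
#'
#' @param kernel a `DoseVoxelKernel`.
#' @return Energy in MeV per history.
#' @export
dvk_total_energy_mev <- function(kernel) {
  mass_kg <- prod(kernel$spacing) * 1e-6
  sum(kernel$values) * mass_kg / 1.602176634e-13
}

#' Write / read a kernel as NIfTI plus JSON sidecar
#'
#' @param kernel a `DoseVoxelKernel`.
#' @param path output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  g <- voxel_grid(kernel$values, kernel$spacing, unit = "Gy/history")
  write_volume(g, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(spacing = kernel$spacing,
                            histories = kernel$histories,
                            central_rel_unc = kernel$central_rel_unc,
                            method = kernel$method),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  g <- read_volume(path, expected_unit = "Gy/history")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(histories = NA, central_rel_unc = NA, method = "file")
  new_dvk(g$values, g$spacing, meta$histories,
          meta$central_rel_unc %||% NA_real_, meta$method %||% "file")
}
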