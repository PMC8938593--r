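# Rasterize a random branching-segment tree into a concentration lattice.
# Segments carry multiplicative lognormal weights (heterogeneous
# vascular-tree-like deposition); growth is clipped at the liver surface.
deposit_tree <- function(dims, spacing, origin, inside_fun, start, start_dir,
                         len0, max_level = 8, branch_prob = 0.85,
                         sdlog = 1.1, step = 0.4) {
  acc <- numeric(prod(dims))
  queue <- list(list(p = start, dir = start_dir / sqrt(sum(start_dir^2)),
                     len = len0, w = 1, level = 1L))
  pts <- list(); wts <- list(); np <- 0L
  while (length(queue)) {
    seg <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    n_step <- max(1L, ceiling(seg$len / step))
    t_ <- seq_len(n_step) * (seg$len / n_step)
    path <- cbind(seg$p[1] + seg$dir[1] * t_, seg$p[2] + seg$dir[2] * t_,
                  seg$p[3] + seg$dir[3] * t_)
    ok <- inside_fun(path)
    if (!all(ok)) {
      stopi <- which(!ok)[1]
      if (stopi == 1L) next
      path <- path[seq_len(stopi - 1L), , drop = FALSE]
    }
    np <- np + 1L
    pts[[np]] <- path
    wts[[np]] <- rep(seg$w * (seg$len / n_step), nrow(path))
    endp <- path[nrow(path), ]
    if (seg$level < max_level && nrow(path) == n_step) {
      for (child in 1:2) {
        if (runif(1) > branch_prob && child == 2L) next
        ang <- abs(rnorm(1, 30, 10)) * pi / 180
        az <- runif(1, 0, 2 * pi)
        dir <- rotate_dir(seg$dir, ang, az)
        queue[[length(queue) + 1L]] <-
          list(p = endp, dir = dir, len = seg$len * 0.8,
               w = seg$w * exp(rnorm(1, 0, sdlog)), level = seg$level + 1L)
      }
    }
  }
  if (np == 0L) stop("deposition tree escaped the liver mask")
  path <- do.call(rbind, pts)
  w <- unlist(wts)
  idx <- cbind(floor((path[, 1] - origin[1]) / spacing[1]) + 1,
               floor((path[, 2] - origin[2]) / spacing[2]) + 1,
               floor((path[, 3] - origin[3]) / spacing[3]) + 1)
  keep <- idx[, 1] >= 1 & idx[, 1] <= dims[1] & idx[, 2] >= 1 &
    idx[, 2] <= dims[2] & idx[, 3] >= 1 & idx[, 3] <= dims[3]
  idx <- idx[keep, , drop = FALSE]
  w <- w[keep]
  if (!length(w)) stop("deposition tree escaped the liver mask")
  lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
  dep <- rowsum(w, lin)
  acc[as.numeric(rownames(dep))] <- dep[, 1]
  array(acc, dims)
}

rotate_dir <- function(u, theta, phi) {
  ct <- cos(theta); st <- sin(theta); cp <- cos(phi); sp <- sin(phi)
  if (abs(u[3]) > 0.99999) {
    v <- c(st * cp, st * sp, sign(u[3]) * ct)
  } else {
    den <- sqrt(1 - u[3]^2)
    v <- c(u[1] * ct + st * (u[1] * u[3] * cp - u[2] * sp) / den,
           u[2] * ct + st * (u[2] * u[3] * cp + u[1] * sp) / den,
           u[3] * ct - den * st * cp)
  }
  v / sqrt(sum(v^2))
}

box_taps <- function(width_mm, spacing_mm) {
  if (width_mm <= 0) return(1)
  h <- ceiling((width_mm / 2) / spacing_mm + 0.5)
  j <- -h:h
  lo <- pmax((j - 0.5) * spacing_mm, -width_mm / 2)
  hi <- pmin((j + 0.5) * spacing_mm, width_mm / 2)
  k <- pmax(hi - lo, 0) / width_mm
  k / sum(k)
}

#' Generate a virtual radioembolization subject
#'
#' Builds a ground-truth microsphere/activity distribution inside an
#' ellipsoidal liver by depositing the administered activity along a
#' random branching-segment tree with branch-wise lognormal concentration
#' multipliers (highly heterogeneous, vascular-tree-like), then simulates
#' both imaging chains:
#' \itemize{
#'   \item CT: forward affine model `HU = m_cal * concentration + mu_bkg`
#'     inside the liver (soft tissue outside, air beyond the body), an
#'     optional smooth contrast-nonuniformity gradient, Gaussian PSF and
#'     additive Gaussian noise, on a fine anisotropic grid.
#'   \item PET: the truth activity aggregated onto a coarser isotropic
#'     grid, converted to Bq/mL, blurred by the system PSF
#'     (`pet_fwhm`), averaged over a cranial-caudal respiratory
#'     displacement of width `resp_amplitude`, with optional noise and a
#'     positivity-truncation bias.
#' }
#' Structure masks are drawn on the CT grid: liver `L`, `L_shell` (`L`
#' plus a 1 cm isotropic margin), a body outline `B`, and a non-embolized
#' background sphere `L_bkg` placed where the local deposition is lowest.
#' The generator bookkeeping guarantees the truth activity sums exactly to
#' `A0`.
#'
#' @param liver_volume_ml liver volume in mL (study range ~65-97).
#' @param A0_bq administered activity in Bq.
#' @param mu_bkg_hu mean liver parenchyma HU (study range ~69-110).
#' @param ct_noise_hu CT noise SD in HU (~3-6; 0 gives a noiseless CT).
#' @param ct_nonuniformity_hu amplitude of a linear contrast-uptake
#'   gradient across the liver, HU.
#' @param ct_psf_fwhm_mm CT PSF FWHM in mm.
#' @param m_cal_true ground-truth calibration slope, HU/(mg/mL).
#' @param A_MS,MS_mg per-sphere activity (Bq) and spheres per mg.
#' @param pet_fwhm_mm PET system blur FWHM in mm (reported range 5-10).
#' @param resp_amplitude_mm full width of the cranial-caudal respiratory
#'   displacement in mm (<= 10 observed).
#' @param pet_noise_frac Gaussian PET noise as a fraction of the mean
#'   in-liver concentration (0 disables noise).
#' @param pet_positivity truncate negative PET values (reconstruction
#'   positivity bias); only meaningful with noise.
#' @param ct_spacing,pet_spacing grid spacings in mm.
#' @param shell_margin_mm isotropic `L_shell` margin.
#' @param tree deposition-tree parameters: `max_level`, `branch_prob`,
#'   `sdlog`, `micro_blur_fwhm` (mm), and the diffuse perfusion component
#'   `diffuse_frac` / `diffuse_fwhm` (mm) — defaults calibrated so the
#'   CT-grid liver dose COV is near 2.
#' @param seed integer seed; fixed seed gives a bit-identical subject.
#' @return Object of class `VirtualSubject`: `truth_activity` (Bq,
#'   CT grid), `ct` (HU), `pet` (Bq/mL, PET grid), `masks`
#'   (`L`, `L_shell`, `L_bkg`, `B` on the CT grid), `record`
#'   (a [subject_record()]), and `truth` (generator bookkeeping).
#' @export
generate_virtual_subject <- function(liver_volume_ml = 79,
                                     A0_bq = 144.2e6,
                                     mu_bkg_hu = 95,
                                     ct_noise_hu = 4,
                                     ct_nonuniformity_hu = 5,
                                     ct_psf_fwhm_mm = 1,
                                     m_cal_true = 14.13,
                                     A_MS = 156, MS_mg = 24460,
                                     pet_fwhm_mm = 7,
                                     resp_amplitude_mm = 10,
                                     pet_noise_frac = 0,
                                     pet_positivity = FALSE,
                                     ct_spacing = c(0.313, 0.313, 2.0),
                                     pet_spacing = c(2.039, 2.039, 2.039),
                                     shell_margin_mm = 10,
                                     tree = list(),
                                     seed = NULL) {
  stopifnot(liver_volume_ml > 10, liver_volume_ml < 500, A0_bq > 0,
            resp_amplitude_mm >= 0, pet_fwhm_mm >= 0, ct_noise_hu >= 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- utils::modifyList(list(max_level = 9L, branch_prob = 0.85,
                               sdlog = 0.5, micro_blur_fwhm = 1.0,
                               diffuse_frac = 0.65, diffuse_fwhm = 18), tree)

  # ellipsoidal liver, semi-axis ratios 1.3 : 1 : 0.77
  s <- (liver_volume_ml * 1000 / (4 / 3 * pi * 1.3 * 0.77))^(1 / 3)
  semi <- s * c(1.3, 1, 0.77)
  body_margin <- 15
  half <- semi + body_margin + 5
  dims <- 2L * as.integer(ceiling(half / ct_spacing))
  origin <- -dims * ct_spacing / 2
  cc <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * ct_spacing[a])
  ell2 <- function(scale) {
    xe <- (cc[[1]] / (semi[1] * scale[1]))^2
    ye <- (cc[[2]] / (semi[2] * scale[2]))^2
    ze <- (cc[[3]] / (semi[3] * scale[3]))^2
    outer(outer(xe, ye, `+`), ze, `+`)
  }
  ref <- voxel_grid(array(0, dims), ct_spacing, origin, unit = "HU")
  L <- structure_mask(ell2(c(1, 1, 1)) <= 1, ref)
  B <- structure_mask(ell2((semi + body_margin) / semi) <= 1, ref)
  L_shell <- expand_mask(L, shell_margin_mm)

  # ground-truth deposition
  inside_fun <- function(p)
    (p[, 1] / semi[1])^2 + (p[, 2] / semi[2])^2 + (p[, 3] / semi[3])^2 <= 1
  dep <- deposit_tree(dims, ct_spacing, origin, inside_fun,
                      start = c(-0.92 * semi[1], 0, 0),
                      start_dir = c(1, 0.15, 0.1),
                      len0 = 0.6 * s, max_level = tr$max_level,
                      branch_prob = tr$branch_prob, sdlog = tr$sdlog)
  if (tr$micro_blur_fwhm > 0)
    dep <- blur_grid_values(dep, ct_spacing, tr$micro_blur_fwhm)
  dep[!L$voxels] <- 0
  if (sum(dep) <= 0) stop("deposition tree escaped the liver mask")
  if (tr$diffuse_frac > 0) {
    # diffuse perfusion component: the same arterial pattern smoothed to
    # lobar scale, so low-concentration deposition fills the territory
    smooth <- blur_grid_values(dep, ct_spacing, tr$diffuse_fwhm)
    smooth[!L$voxels] <- 0
    dep <- (1 - tr$diffuse_frac) * dep +
      tr$diffuse_frac * smooth * (sum(dep) / sum(smooth))
  }
  dep <- dep * (A0_bq / sum(dep))  # exact bookkeeping: sum(truth) == A0
  truth <- voxel_grid(dep, ct_spacing, origin, unit = "Bq")

  # background region: the candidate sphere with the least deposition
  r_bkg <- min(6, 0.3 * min(semi))
  cand <- rbind(c(0.55, 0, 0), c(-0.55, 0, 0), c(0, 0.55, 0), c(0, -0.55, 0),
                c(0.4, 0.4, 0), c(-0.4, -0.4, 0), c(0.4, -0.4, 0),
                c(-0.4, 0.4, 0)) * matrix(semi, 8, 3, byrow = TRUE)
  best <- NULL; best_sum <- Inf
  for (i in seq_len(nrow(cand))) {
    d2 <- outer(outer((cc[[1]] - cand[i, 1])^2, (cc[[2]] - cand[i, 2])^2, `+`),
                (cc[[3]] - cand[i, 3])^2, `+`)
    vox <- d2 <= r_bkg^2 & L$voxels
    if (!any(vox)) next
    ssum <- sum(dep[vox])
    if (ssum < best_sum) { best_sum <- ssum; best <- vox }
  }
  L_bkg <- structure_mask(best, ref)

  # CT chain: forward affine model + nonuniformity + PSF + noise
  v_ml <- prod(ct_spacing) / 1000
  conc <- dep / (MS_mg * A_MS * v_ml)
  hu <- array(-1000, dims)
  hu[B$voxels] <- 40
  hu[L$voxels] <- mu_bkg_hu + m_cal_true * conc[L$voxels]
  if (ct_nonuniformity_hu > 0) {
    gx <- array(rep(cc[[1]] / half[1], times = dims[2] * dims[3]), dims)
    hu[L$voxels] <- hu[L$voxels] + ct_nonuniformity_hu * gx[L$voxels]
  }
  if (ct_psf_fwhm_mm > 0) hu <- blur_grid_values(hu, ct_spacing, ct_psf_fwhm_mm)
  if (ct_noise_hu > 0) hu <- hu + array(rnorm(length(hu), 0, ct_noise_hu), dims)
  ct <- voxel_grid(hu, ct_spacing, origin, unit = "HU")

  # PET chain: aggregate truth to the PET grid, blur, smear, noise
  pet_spacing <- rep_len(pet_spacing, 3)
  pdims <- 2L * as.integer(ceiling((half + 10) / pet_spacing))
  porigin <- -pdims * pet_spacing / 2
  idx <- lapply(1:3, function(a)
    pmin(pmax(floor((cc[[a]] - porigin[a]) / pet_spacing[a]) + 1, 1), pdims[a]))
  td <- dims
  ii <- idx[[1]][slice.index(array(0L, td), 1)]
  jj <- idx[[2]][slice.index(array(0L, td), 2)]
  kk <- idx[[3]][slice.index(array(0L, td), 3)]
  lin <- (as.numeric(kk) - 1) * pdims[1] * pdims[2] + (as.numeric(jj) - 1) * pdims[1] + ii
  pvals <- numeric(prod(pdims))
  agg <- rowsum(as.numeric(dep), lin)
  pvals[as.numeric(rownames(agg))] <- agg[, 1]
  pvals <- array(pvals / (prod(pet_spacing) / 1000), pdims)  # Bq -> Bq/mL
  if (pet_fwhm_mm > 0) pvals <- blur_grid_values(pvals, pet_spacing, pet_fwhm_mm)
  if (resp_amplitude_mm > 0)
    pvals <- array(sep_conv3(as.numeric(pvals), pdims, 1, 1,
                             box_taps(resp_amplitude_mm, pet_spacing[3])), pdims)
  if (pet_noise_frac > 0) {
    lev <- pet_noise_frac * mean(pvals[pvals > 0])
    pvals <- pvals + array(rnorm(length(pvals), 0, lev), pdims)
    if (pet_positivity) pvals[pvals < 0] <- 0
  }
  pet <- voxel_grid(pvals, pet_spacing, porigin, unit = "Bq/mL")

  masks <- list(L = L, L_shell = L_shell, L_bkg = L_bkg, B = B)
  record <- subject_record(A0 = A0_bq, residual_fraction = 0,
                           A_MS = A_MS, MS_mg = MS_mg, masks = masks)
  structure(list(truth_activity = truth, ct = ct, pet = pet, masks = masks,
                 record = record,
                 truth = list(A0_bq = A0_bq, m_cal_true = m_cal_true,
                              mu_bkg_hu = mu_bkg_hu,
                              liver_volume_ml = mask_volume_ml(L),
                              semi_axes_mm = semi, seed = seed)),
            class = "VirtualSubject")
}

#' @export
print.VirtualSubject <- function(x, ...) {
  cat(sprintf("<VirtualSubject> liver %.1f mL, A0 %.1f MBq, CT %s, PET %s\n",
              x$truth$liver_volume_ml, x$truth$A0_bq / 1e6,
              paste(dim(x$ct$values), collapse = "x"),
              paste(dim(x$pet$values), collapse = "x")))
  invisible(x)
}
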