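#' Calibration-phantom description
#'
#' Describes the multi-post CT calibration phantom: cylindrical posts of
#' microsphere-infused resin, nine posts per concentration (diameters 2-9 mm
#' in 1 mm steps plus one 15 mm post), all post axes equidistant from the
#' phantom's central axis, embedded in a uniform resin background. The
#' generator's ground truth is the affine HU model
#' `HU = true_slope * concentration + background_mu`.
#'
#' @param post_diameters post diameters in mm.
#' @param concentrations microsphere concentrations in mg/mL.
#' @param post_length post length in mm.
#' @param post_axis_radius distance (mm) of every post axis from the
#'   phantom's central axis.
#' @param background_radius radius (mm) of the resin background disc.
#' @param background_mu mean background HU. The phantom analyses work in
#'   background-subtracted (delta-HU) terms, so 0 is the natural default.
#' @param background_sigma CT noise standard deviation in HU.
#' @param true_slope ground-truth HU per mg/mL.
#' @param psf_fwhm in-plane/axial CT PSF FWHM in mm (0 disables blur).
#' @param spacing CT voxel spacing in mm.
#' @param seed integer seed; the generated volume is bit-identical for a
#'   fixed seed.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(post_diameters = c(2:9, 15),
                         concentrations = c(0.5, 5.0, 25.0),
                         post_length = 40,
                         post_axis_radius = 100,
                         background_radius = 150,
                         background_mu = 0,
                         background_sigma = 4,
                         true_slope = 14.13,
                         psf_fwhm = 1,
                         spacing = c(0.313, 0.313, 2.0),
                         seed = NULL) {
  stopifnot(all(post_diameters > 0), all(concentrations >= 0),
            post_length > 0, post_axis_radius > 0,
            background_sigma >= 0, psf_fwhm >= 0, all(spacing > 0))
  structure(list(post_diameters = post_diameters,
                 concentrations = concentrations,
                 post_length = post_length,
                 post_axis_radius = post_axis_radius,
                 background_radius = background_radius,
                 background_mu = background_mu,
                 background_sigma = background_sigma,
                 true_slope = true_slope,
                 psf_fwhm = psf_fwhm,
                 spacing = spacing,
                 seed = seed),
            class = "PhantomSpec")
}

gauss_taps <- function(sigma_mm, spacing_mm) {
  if (sigma_mm <= 0) return(1)
  h <- ceiling(4 * sigma_mm / spacing_mm)
  k <- exp(-((-h:h) * spacing_mm)^2 / (2 * sigma_mm^2))
  k / sum(k)
}

blur_grid_values <- function(values, spacing, fwhm_mm) {
  if (all(fwhm_mm <= 0)) return(values)
  fwhm_mm <- rep_len(fwhm_mm, 3)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- sep_conv3(as.numeric(values), dim(values),
                   gauss_taps(sig[1], spacing[1]),
                   gauss_taps(sig[2], spacing[2]),
                   gauss_taps(sig[3], spacing[3]))
  array(out, dim(values))
}

#' Generate a synthetic calibration-phantom CT
#'
#' Posts are rasterized as `true_slope * concentration + background_mu`
#' inside their cylinders and `background_mu` elsewhere, then blurred by a
#' Gaussian PSF of `psf_fwhm` and corrupted with additive Gaussian noise of
#' `background_sigma` HU. The grid covers the ring of posts plus a margin;
#' everything inside it is background resin, so there is no air interface.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `PhantomCT` with elements `ct` (a [voxel_grid()]
#'   in HU) and `posts` (a data frame with one row per post: centre
#'   coordinates, diameter, length, concentration).
#' @export
generate_phantom_ct <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nd <- length(spec$post_diameters)
  nc <- length(spec$concentrations)
  npost <- nd * nc
  ang <- 2 * pi * (seq_len(npost) - 1) / npost
  # adjacent posts must not overlap on the ring (1 mm clearance)
  dia <- rep(spec$post_diameters, times = nc)
  gap <- 2 * spec$post_axis_radius * sin(pi / npost)
  need <- (dia + c(dia[-1], dia[1])) / 2 + 1
  if (any(gap < need))
    stop("post geometry infeasible: posts overlap on the ring")
  posts <- data.frame(
    post = seq_len(npost),
    x_mm = spec$post_axis_radius * cos(ang),
    y_mm = spec$post_axis_radius * sin(ang),
    diameter_mm = dia,
    length_mm = spec$post_length,
    concentration_mg_ml = rep(spec$concentrations, each = nd))

  sp <- spec$spacing
  half_xy <- spec$post_axis_radius + max(spec$post_diameters) / 2 + 8
  half_xy <- min(half_xy, spec$background_radius)
  half_z <- spec$post_length / 2 + 2 * sp[3]
  dims <- c(2 * ceiling(half_xy / sp[1]), 2 * ceiling(half_xy / sp[2]),
            2 * ceiling(half_z / sp[3]))
  origin <- -dims * sp / 2
  vals <- array(spec$background_mu, dims)
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * sp[1]
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * sp[2]
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * sp[3]
  zin <- which(abs(zc) <= spec$post_length / 2)
  half_diag <- sqrt(sum((sp[1:2] / 2)^2))
  for (p in seq_len(npost)) {
    r <- posts$diameter_mm[p] / 2
    ix <- which(abs(xc - posts$x_mm[p]) <= r + half_diag)
    iy <- which(abs(yc - posts$y_mm[p]) <= r + half_diag)
    if (!length(ix) || !length(iy)) next
    d <- sqrt(outer((xc[ix] - posts$x_mm[p])^2, (yc[iy] - posts$y_mm[p])^2, `+`))
    # partial-volume rasterization: boundary voxels weighted by the
    # in-plane coverage fraction (5x5 supersampling) so the deposited
    # microsphere mass matches the analytic cylinder mass
    cov <- matrix(0, length(ix), length(iy))
    cov[d <= r - half_diag] <- 1
    edge <- which(d > r - half_diag & d < r + half_diag, arr.ind = TRUE)
    if (nrow(edge)) {
      off <- (seq_len(5) - 3) / 5
      sub <- expand.grid(ox = off * sp[1], oy = off * sp[2])
      for (e in seq_len(nrow(edge))) {
        px <- xc[ix[edge[e, 1]]] + sub$ox
        py <- yc[iy[edge[e, 2]]] + sub$oy
        cov[edge[e, 1], edge[e, 2]] <-
          mean((px - posts$x_mm[p])^2 + (py - posts$y_mm[p])^2 <= r^2)
      }
    }
    add <- spec$true_slope * posts$concentration_mg_ml[p] * cov
    for (k in zin) vals[ix, iy, k] <- vals[ix, iy, k] + add
  }
  if (spec$psf_fwhm > 0) vals <- blur_grid_values(vals, sp, spec$psf_fwhm)
  if (spec$background_sigma > 0)
    vals <- vals + array(rnorm(length(vals), 0, spec$background_sigma), dims)
  structure(list(ct = voxel_grid(vals, spacing = sp, origin = origin, unit = "HU"),
                 posts = posts, spec = spec),
            class = "PhantomCT")
}
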