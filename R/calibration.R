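#' Segment calibration-phantom posts from known geometry
#'
#' Builds one analytic cylinder mask per post on the CT grid, reduced by a
#' radial and a longitudinal margin to strip partial-volume layers. Posts
#' whose diameter is `<= 2 * radial` cannot survive the radial margin and
#' are instead replaced by a `thin_post_diameter` cylinder centred on the
#' post axis. A central background cylinder (`bkg_diameter`) samples the
#' microsphere-free resin.
#'
#' @param phantom a `PhantomCT` from [generate_phantom_ct()], or a list
#'   with elements `ct` (a [voxel_grid()]) and `posts` (geometry records).
#' @param radial radial margin in mm.
#' @param longitudinal margin removed from each post end in mm.
#' @param thin_post_diameter replacement diameter (mm) for posts too thin
#'   to erode.
#' @param bkg_diameter diameter (mm) of the central background cylinder.
#' @return List with `posts` (list of [structure_mask()], one per post row),
#'   `background` (a [structure_mask()]) and the reduced geometry table.
#' @export
segment_posts <- function(phantom, radial = 1, longitudinal = 5,
                          thin_post_diameter = 1, bkg_diameter = 30) {
  ct <- phantom$ct
  geo <- phantom$posts
  cc <- voxel_centers(ct)
  zin <- abs(cc[[3]]) <= (geo$length_mm[1] - 2 * longitudinal) / 2
  if (!any(zin)) stop("longitudinal margin emptied the posts")
  cyl_mask <- function(x0, y0, r) {
    d2 <- outer((cc[[1]] - x0)^2, (cc[[2]] - y0)^2, `+`)
    disc <- d2 <= r^2
    vox <- array(FALSE, dim(ct$values))
    for (k in which(zin)) vox[, , k] <- disc
    vox
  }
  red_r <- ifelse(geo$diameter_mm / 2 - radial > 0,
                  geo$diameter_mm / 2 - radial, thin_post_diameter / 2)
  masks <- lapply(seq_len(nrow(geo)), function(p) {
    vox <- cyl_mask(geo$x_mm[p], geo$y_mm[p], red_r[p])
    if (!any(vox)) stop("post ", p, " mask is empty after reduction")
    structure_mask(vox, ct)
  })
  bkg <- structure_mask(cyl_mask(0, 0, bkg_diameter / 2), ct)
  geo$reduced_diameter_mm <- 2 * red_r
  geo$reduced_length_mm <- geo$length_mm - 2 * longitudinal
  list(posts = masks, background = bkg, geometry = geo)
}

#' Mean HU per post
#'
#' Arithmetic mean of the CT values inside each reduced post mask, the fit
#' points for [fit_calibration()].
#'
#' @param phantom a `PhantomCT`.
#' @param segmentation result of [segment_posts()].
#' @return Data frame with one row per post: diameter, concentration,
#'   mean and population SD of HU, voxel count.
#' @export
post_mean_table <- function(phantom, segmentation) {
  geo <- segmentation$geometry
  stats <- lapply(segmentation$posts, function(m) mask_stats(phantom$ct, m))
  data.frame(post = geo$post,
             diameter_mm = geo$diameter_mm,
             concentration_mg_ml = geo$concentration_mg_ml,
             mean_hu = vapply(stats, `[[`, numeric(1), "mu"),
             sd_hu = vapply(stats, `[[`, numeric(1), "sigma"),
             n_voxels = vapply(stats, `[[`, numeric(1), "n_voxels"))
}

#' Fit the HU-concentration calibration line
#'
#' Ordinary least squares of mean HU on microsphere concentration, with a
#' t-based 95% confidence interval on the slope, the coefficient of
#' determination, and a 95% prediction-interval function.
#'
#' @param points data frame with columns `concentration_mg_ml` and
#'   `mean_hu` (e.g. from [post_mean_table()]), or a two-column matrix.
#' @return Object of class `CalibrationCurve`: `m_cal` (HU per mg/mL),
#'   `m_cal_ci95`, `b_cal` (fitted intercept, HU), `r_squared`,
#'   `prediction_interval_95` (function of concentration returning a
#'   two-column matrix), and `fit_points`.
#' @export
fit_calibration <- function(points) {
  if (is.matrix(points)) points <- data.frame(concentration_mg_ml = points[, 1],
                                              mean_hu = points[, 2])
  x <- points$concentration_mg_ml
  y <- points$mean_hu
  if (length(unique(x)) < 2L) stop("need >= 2 distinct concentrations")
  fit <- lm(mean_hu ~ concentration_mg_ml, data = points)
  sm <- suppressWarnings(summary(fit))  # noiseless phantoms fit exactly
  ci <- if (nrow(points) > 2L)
          suppressWarnings(confint(fit, "concentration_mg_ml", level = 0.95))
        else matrix(rep(coef(fit)[2], 2), 1)
  pi_fun <- function(conc) {
    p <- suppressWarnings(
      predict(fit, newdata = data.frame(concentration_mg_ml = conc),
              interval = "prediction", level = 0.95))
    p[, c("lwr", "upr"), drop = FALSE]
  }
  structure(list(m_cal = unname(coef(fit)[2]),
                 m_cal_ci95 = as.numeric(ci),
                 b_cal = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 prediction_interval_95 = pi_fun,
                 fit_points = points[, c("concentration_mg_ml", "mean_hu")],
                 fit = fit),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf("<CalibrationCurve> m_cal = %.3f HU/(mg/mL) [95%% CI %.3f, %.3f], b = %.2f HU, r^2 = %.5f\n",
              x$m_cal, x$m_cal_ci95[1], x$m_cal_ci95[2], x$b_cal, x$r_squared))
  invisible(x)
}

#' Background statistics of a non-embolized region
#'
#' @param grid HU [voxel_grid()].
#' @param mask background [structure_mask()] (`L_bkg` or the phantom's
#'   central cylinder).
#' @return Object of class `BackgroundStats` with `mu_bkg`, `sigma_bkg`
#'   (population SD) and `n_voxels`; warns below 30 voxels.
#' @export
background_stats <- function(grid, mask) {
  s <- mask_stats(grid, mask)
  if (s$n_voxels < 30) warning("background region has fewer than 30 voxels")
  structure(list(mu_bkg = s$mu, sigma_bkg = s$sigma, n_voxels = s$n_voxels),
            class = "BackgroundStats")
}

#' Per-subject calibration intercept
#'
#' The intercept is placed at the one-sided 95% point of the background HU
#' distribution, `mu_bkg + 1.645 * sigma_bkg`, so that voxels above it have
#' a 95% probability of containing microspheres.
#'
#' @param bkg a [background_stats()] result, or a list with `mu_bkg` and
#'   `sigma_bkg`.
#' @return Intercept in HU.
#' @export
compute_intercept <- function(bkg) {
  stopifnot(is.finite(bkg$mu_bkg), is.finite(bkg$sigma_bkg), bkg$sigma_bkg >= 0)
  bkg$mu_bkg + 1.645 * bkg$sigma_bkg
}

#' Calibration slope per post diameter
#'
#' Fits the calibration line separately within each post diameter and flags
#' diameters whose slope falls outside the 95% CI of the pooled fit
#' (partial-volume bias shows up in the thinnest posts).
#'
#' @param points per-post fit points from [post_mean_table()].
#' @return Data frame: diameter, slope, 95% CI bounds, r-squared, and
#'   `outside_pooled_ci`.
#' @export
slope_by_diameter <- function(points) {
  pooled <- fit_calibration(points)
  by_d <- split(points, points$diameter_mm)
  rows <- lapply(by_d, function(df) {
    if (length(unique(df$concentration_mg_ml)) < 2L)
      stop("diameter ", df$diameter_mm[1], " has < 2 concentrations")
    f <- fit_calibration(df)
    data.frame(diameter_mm = df$diameter_mm[1], slope = f$m_cal,
               ci_lo = f$m_cal_ci95[1], ci_hi = f$m_cal_ci95[2],
               r_squared = f$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$outside_pooled_ci <- out$slope < pooled$m_cal_ci95[1] |
    out$slope > pooled$m_cal_ci95[2]
  attr(out, "pooled") <- pooled
  out[order(out$diameter_mm), ]
}
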