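#' Per-structure dose statistics
#'
#' Median, maximum and mean dose, population standard deviation, COV
#' (`sigma / D_mu`) and D70 over the voxels of a structure.
#'
#' @param dose Gy [voxel_grid()].
#' @param mask non-empty [structure_mask()] on the dose grid.
#' @return Object of class `DoseReport`: `D_med`, `D_max`, `D_mu`, `sigma`,
#'   `COV`, `D70`, `n_voxels`.
#' @export
dose_stats <- function(dose, mask) {
  s <- mask_stats(dose, mask)
  v <- dose$values[mask$voxels]
  structure(list(D_med = median(v), D_max = max(v), D_mu = s$mu,
                 sigma = s$sigma,
                 COV = if (s$mu > 0) s$sigma / s$mu else NA_real_,
                 D70 = d_x(dose, mask, 70), n_voxels = s$n_voxels),
            class = "DoseReport")
}

#' @export
print.DoseReport <- function(x, ...) {
  cat(sprintf("<DoseReport> D_med %.2f, D_max %.2f, D_mu %.2f, sigma %.2f, COV %.2f, D70 %.2f Gy (%d voxels)\n",
              x$D_med, x$D_max, x$D_mu, x$sigma, x$COV, x$D70, x$n_voxels))
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the masked volume receiving at least each dose-bin edge,
#' computed exactly from the sorted voxel doses: non-increasing, starting
#' at 1 at zero dose.
#'
#' @param dose Gy [voxel_grid()].
#' @param mask non-empty [structure_mask()].
#' @param bins number of bin edges (>= 2); edges span 0 to the maximum
#'   voxel dose.
#' @return Object of class `CumulativeDVH`: `dose_gy` (edges) and
#'   `volume_fraction`.
#' @export
cdvh <- function(dose, mask, bins = 200) {
  stopifnot(bins >= 2)
  v <- dose$values[mask$voxels]
  if (!length(v)) stop("mask is empty")
  edges <- seq(0, max(v), length.out = bins)
  vs <- sort(v)
  n <- length(vs)
  # count of voxels with dose >= edge via binary search on the sorted doses
  frac <- 1 - (findInterval(edges, vs, left.open = TRUE)) / n
  structure(list(dose_gy = edges, volume_fraction = frac),
            class = "CumulativeDVH")
}

#' Dose covering x percent of a structure
#'
#' `D_x` is the largest dose received by at least `x`% of the masked
#' volume: the `ceiling(x% * n)`-th voxel dose counted from the top, with
#' no interpolation (exact order statistic).
#'
#' @param dose Gy [voxel_grid()].
#' @param mask non-empty [structure_mask()].
#' @param x coverage percentage in `(0, 100]`.
#' @return Dose in Gy.
#' @export
d_x <- function(dose, mask, x) {
  stopifnot(x > 0, x <= 100)
  v <- dose$values[mask$voxels]
  if (!length(v)) stop("mask is empty")
  k <- ceiling(x / 100 * length(v))
  sort(v, decreasing = TRUE)[k]
}

#' CT detectability limits: LOB, LOD and MDA
#'
#' One-sided 95% detection chain: the limit of blank is
#' `LOB = mu + 1.645 sigma` of the background (with `mu = 0` in
#' background-subtracted delta-HU mode); the limit of detection adds the
#' spread of a known low-concentration sample, `LOD_HU = LOB +
#' 1.645 sigma_low`; converting through the calibration line gives
#' `LOD_conc = (LOD_HU - b_cal) / m_cal`, and the minimum detectable
#' activity concentration is `MDA = LOD_conc * MS_mg * A_MS` (Bq/mL).
#' The intercept `b_cal` is itself the one-sided 95% point of the same
#' background, i.e. equal to the LOB.
#'
#' @param bkg [background_stats()] of the microsphere-free region.
#' @param sigma_low_conc HU standard deviation of the low-concentration
#'   replicates (the 0.5 mg/mL posts).
#' @param curve a [fit_calibration()] result (or slope in HU/(mg/mL)).
#' @param record a [subject_record()] supplying `MS_mg` and `A_MS`.
#' @param delta_hu treat the background as baseline-subtracted
#'   (`mu_bkg = 0`); default `TRUE`, the phantom analysis mode.
#' @return Object of class `DetectabilityResult`: `lob_hu`, `lod_hu`,
#'   `lod_conc`, `mda_bq_ml`.
#' @export
detectability <- function(bkg, sigma_low_conc, curve, record,
                          delta_hu = TRUE) {
  m_cal <- if (inherits(curve, "CalibrationCurve")) curve$m_cal else as.numeric(curve)
  if (!is.finite(m_cal) || m_cal <= 0) stop("m_cal must be > 0")
  stopifnot(sigma_low_conc >= 0)
  mu <- if (delta_hu) 0 else bkg$mu_bkg
  lob <- mu + 1.645 * bkg$sigma_bkg
  lod_hu <- lob + 1.645 * sigma_low_conc
  b_cal <- lob
  lod_conc <- (lod_hu - b_cal) / m_cal
  structure(list(lob_hu = lob, lod_hu = lod_hu, lod_conc = lod_conc,
                 mda_bq_ml = lod_conc * record$MS_mg * record$A_MS),
            class = "DetectabilityResult")
}

#' Fraction of activity near a structure's boundary
#'
#' Percentage of the in-mask activity held by voxels whose centre lies
#' within `depth` mm of the mask's exterior boundary (distance to the
#' nearest outside voxel, via the physical-unit distance transform).
#' With `depth` set to the mean or maximum beta range this measures how
#' much dose can spill outside the contour.
#'
#' @param activity Bq [voxel_grid()].
#' @param mask non-empty [structure_mask()] on the activity grid.
#' @param depth shell depth in mm (>= 0).
#' @return Percentage in `[0, 100]`.
#' @export
boundary_activity_fraction <- function(activity, mask, depth) {
  stopifnot(inherits(activity, "VoxelGrid"), inherits(mask, "StructureMask"),
            depth >= 0)
  if (!any(mask$voxels)) stop("mask is empty")
  tot <- sum(activity$values[mask$voxels])
  if (tot == 0) return(0)
  outside <- mask
  outside$voxels <- !mask$voxels
  outside$values <- outside$voxels
  if (!any(outside$voxels)) return(0)  # mask fills the grid: no boundary
  d <- distance_to_mask(outside)
  shell <- mask$voxels & d <= depth + 1e-9
  100 * sum(activity$values[shell]) / tot
}

#' Dose-metrics table for a set of structures
#'
#' One [dose_stats()] row per structure, shaped like a per-subject
#' dose-metrics report.
#'
#' @param dose Gy [voxel_grid()].
#' @param masks named list of [structure_mask()]s.
#' @return Data frame with one row per structure.
#' @export
dose_metrics_by_structure <- function(dose, masks) {
  rows <- lapply(names(masks), function(nm) {
    r <- dose_stats(dose, masks[[nm]])
    data.frame(structure = nm, D_med = r$D_med, D_max = r$D_max,
               D_mu = r$D_mu, sigma = r$sigma, COV = r$COV, D70 = r$D70,
               n_voxels = r$n_voxels)
  })
  do.call(rbind, rows)
}
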