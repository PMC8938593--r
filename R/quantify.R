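#' Subject administration record
#'
#' Bundles the per-subject scalars needed to turn microsphere
#' concentration into activity: administered activity, fractional residual
#' activity, per-microsphere activity, microspheres per milligram, and the
#' structure masks.
#'
#' @param A0 administered Y-90 activity in Bq (> 0).
#' @param residual_fraction fractional residual activity R in `[0, 1)`.
#'   Defaults to 0, i.e. `A0` is already net of residuals.
#' @param A_MS activity per microsphere in Bq (> 0).
#' @param MS_mg microspheres per milligram (> 0).
#' @param masks named list of [structure_mask()]s by role
#'   (`L`, `L_shell`, `L_bkg`, `B`), optional.
#' @return Object of class `SubjectRecord`.
#' @export
subject_record <- function(A0, residual_fraction = 0, A_MS = 156,
                           MS_mg = 24460, masks = list()) {
  stopifnot(A0 > 0, A_MS > 0, MS_mg > 0,
            residual_fraction >= 0, residual_fraction < 1)
  structure(list(A0 = A0, residual_fraction = residual_fraction,
                 A_MS = A_MS, MS_mg = MS_mg, masks = masks),
            class = "SubjectRecord")
}

#' Convert a CT volume to microsphere concentration
#'
#' Inverts the calibration line: `conc = (HU - b_cal) / m_cal`. Voxels at
#' or below `b_cal` are clamped to zero concentration by default — the
#' intercept is constructed so that only voxels above it credibly contain
#' microspheres. Voxels outside `mask` (when given) are set to zero.
#'
#' @param ct HU [voxel_grid()].
#' @param curve a [fit_calibration()] result, or a single slope in
#'   HU/(mg/mL).
#' @param intercept intercept b_cal in HU; defaults to the per-subject
#'   value from [compute_intercept()] if a `BackgroundStats` is supplied,
#'   else the curve's fitted intercept.
#' @param mask optional [structure_mask()] restricting the conversion.
#' @param clamp clamp negative concentrations to zero (default `TRUE`).
#'   With `clamp = FALSE` the inversion is exactly affine, which is the
#'   mode used for phantom mass integration.
#' @return A mg/mL [voxel_grid()].
#' @export
ct_to_concentration <- function(ct, curve, intercept = NULL, mask = NULL,
                                clamp = TRUE) {
  stopifnot(inherits(ct, "VoxelGrid"))
  if (ct$unit != "HU") stop("`ct` must carry the HU unit tag")
  m_cal <- if (inherits(curve, "CalibrationCurve")) curve$m_cal else as.numeric(curve)
  if (!is.finite(m_cal) || m_cal <= 0) stop("m_cal must be > 0")
  if (is.null(intercept)) {
    intercept <- if (inherits(curve, "CalibrationCurve")) curve$b_cal else 0
  }
  if (inherits(intercept, "BackgroundStats")) intercept <- compute_intercept(intercept)
  conc <- (ct$values - intercept) / m_cal
  if (clamp) conc[conc < 0] <- 0
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "StructureMask"))
    conc[!mask$voxels] <- 0
  }
  voxel_grid(conc, ct$spacing, ct$origin, unit = "mg/mL")
}

#' Convert microsphere concentration to voxel activity
#'
#' Per-voxel activity in Bq is `conc * MS_mg * A_MS * V` with `V` the voxel
#' volume in mL.
#'
#' @param conc mg/mL [voxel_grid()].
#' @param record a [subject_record()].
#' @return A Bq [voxel_grid()].
#' @export
concentration_to_activity <- function(conc, record) {
  stopifnot(inherits(conc, "VoxelGrid"), inherits(record, "SubjectRecord"))
  if (conc$unit != "mg/mL") stop("`conc` must carry the mg/mL unit tag")
  v_ml <- voxel_volume_ml(conc)
  voxel_grid(conc$values * record$MS_mg * record$A_MS * v_ml,
             conc$spacing, conc$origin, unit = "Bq")
}

#' Recovery coefficient of an activity distribution
#'
#' Percentage of the administered activity recovered inside a structure:
#' `100 * sum(A within mask) / A0`.
#'
#' @param activity Bq [voxel_grid()].
#' @param mask [structure_mask()] on the activity grid.
#' @param A0 administered activity in Bq, or a [subject_record()].
#' @return Recovery coefficient in percent.
#' @export
recovery_coefficient <- function(activity, mask, A0) {
  stopifnot(inherits(activity, "VoxelGrid"), inherits(mask, "StructureMask"))
  if (inherits(A0, "SubjectRecord")) A0 <- A0$A0
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be > 0")
  if (!same_geometry(activity, mask)) stop("mask and grid geometries differ")
  100 * sum(activity$values[mask$voxels]) / A0
}

#' Gaussian post-filter in physical units
#'
#' Separable Gaussian with `sigma = fwhm / 2.3548` along each axis,
#' zero-padded so the total is conserved up to boundary truncation.
#'
#' @param grid a [voxel_grid()] (any unit).
#' @param fwhm full width at half maximum in mm (>= 0; 0 is the identity).
#' @return Filtered [voxel_grid()] of the same unit.
#' @export
gaussian_postfilter <- function(grid, fwhm) {
  stopifnot(inherits(grid, "VoxelGrid"))
  if (!is.finite(fwhm) || fwhm < 0) stop("`fwhm` must be >= 0")
  if (fwhm == 0) return(grid)
  voxel_grid(blur_grid_values(grid$values, grid$spacing, fwhm),
             grid$spacing, grid$origin, unit = grid$unit)
}

#' Convert an activity-concentration volume to per-voxel activity
#'
#' @param pet Bq/mL [voxel_grid()].
#' @return A Bq [voxel_grid()] (`value * voxel volume in mL`).
#' @export
pet_to_activity <- function(pet) {
  stopifnot(inherits(pet, "VoxelGrid"))
  if (pet$unit != "Bq/mL") stop("`pet` must carry the Bq/mL unit tag")
  voxel_grid(pet$values * voxel_volume_ml(pet), pet$spacing, pet$origin,
             unit = "Bq")
}

#' Fraction of activity outside an inner structure
#'
#' `100 * sum(A over outer minus inner) / sum(A over outer)` — e.g. the
#' share of body activity lying beyond the extended liver volume.
#'
#' @param activity Bq [voxel_grid()].
#' @param inner inner [structure_mask()] (must be contained in `outer`).
#' @param outer outer [structure_mask()].
#' @return Percentage of the outer-structure activity outside `inner`.
#' @export
activity_ratio_outside <- function(activity, inner, outer) {
  stopifnot(inherits(activity, "VoxelGrid"))
  if (any(inner$voxels & !outer$voxels))
    stop("`inner` must be a subset of `outer`")
  tot <- sum(activity$values[outer$voxels])
  if (tot == 0) stop("no activity inside `outer`")
  100 * sum(activity$values[outer$voxels & !inner$voxels]) / tot
}
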