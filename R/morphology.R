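#' Euclidean distance map to a mask, in millimetres
#'
#' Distance from every voxel centre to the nearest centre of a voxel in
#' `mask`, computed with an exact anisotropic distance transform in
#' physical units. `axes` restricts the transform to a subset of grid axes
#' (the others are treated as infinitely far apart), which yields radial or
#' longitudinal distances for cylinder margins.
#'
#' @param mask a [structure_mask()].
#' @param axes integer axes (subset of 1:3) along which distance is measured.
#' @return Numeric 3-D array of distances (mm).
#' @export
distance_to_mask <- function(mask, axes = 1:3) {
  stopifnot(inherits(mask, "StructureMask"))
  sp <- mask$spacing
  sp[setdiff(1:3, axes)] <- Inf
  d2 <- edt3d_sq(as.logical(mask$voxels), dim(mask$voxels), sp)
  array(sqrt(d2), dim(mask$voxels))
}

#' Expand a mask by a physical margin
#'
#' The result contains every voxel whose centre lies within `margin`
#' (Euclidean, mm) of a voxel centre in `mask`, so a 1 cm margin on an
#' anisotropic grid grows by different voxel counts per axis.
#'
#' @param mask a [structure_mask()].
#' @param margin isotropic margin in mm (>= 0).
#' @return Expanded [structure_mask()].
#' @export
expand_mask <- function(mask, margin) {
  stopifnot(inherits(mask, "StructureMask"))
  if (!is.finite(margin) || margin < 0) stop("`margin` must be >= 0")
  if (margin == 0) return(mask)
  d <- distance_to_mask(mask)
  out <- mask
  out$voxels <- array(d <= margin + 1e-9, dim(mask$voxels))
  out$values <- out$voxels
  out
}

#' Erode a cylinder-like mask by radial and longitudinal margins
#'
#' Removes voxels whose centre lies within `radial` mm of the lateral
#' (in-plane) surface or within `longitudinal` mm of either end along
#' `axis`, the margin scheme used to strip partial-volume layers from
#' calibration-phantom posts.
#'
#' @param mask a [structure_mask()] approximating a cylinder along `axis`.
#' @param radial radial margin in mm (>= 0).
#' @param longitudinal end margin in mm (>= 0).
#' @param axis grid axis (1, 2 or 3) of the cylinder axis.
#' @return Eroded [structure_mask()]; erroring if the erosion empties the
#'   mask (thin posts need the dedicated 1 mm-cylinder rule in
#'   [segment_posts()]).
#' @export
erode_mask_radial_longitudinal <- function(mask, radial, longitudinal, axis = 3L) {
  stopifnot(inherits(mask, "StructureMask"))
  if (radial < 0 || longitudinal < 0) stop("margins must be >= 0")
  if (radial == 0 && longitudinal == 0) return(mask)
  outside <- mask
  outside$voxels <- !mask$voxels
  outside$values <- outside$voxels
  keep <- mask$voxels
  if (radial > 0) {
    d_rad <- distance_to_mask(outside, axes = setdiff(1:3, axis))
    keep <- keep & (d_rad > radial - 1e-9)
  }
  if (longitudinal > 0) {
    d_lon <- distance_to_mask(outside, axes = axis)
    keep <- keep & (d_lon > longitudinal - 1e-9)
  }
  if (!any(keep))
    stop("erosion emptied the mask; use the thin-post reduction rule instead")
  out <- mask
  out$voxels <- keep
  out$values <- keep
  out
}

#' Resample a mask onto another grid by nearest-centre assignment
#'
#' A target voxel belongs to the resampled mask iff its centre falls inside
#' the physical extent of a source voxel that is in the mask. This is how
#' CT-drawn contours are evaluated on the PET grid.
#'
#' @param mask a [structure_mask()].
#' @param target a [voxel_grid()] whose geometry the result should have.
#' @return A [structure_mask()] on `target` (possibly empty).
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "StructureMask"), inherits(target, "VoxelGrid"))
  src_dim <- dim(mask$voxels)
  tc <- voxel_centers(target)
  idx <- lapply(1:3, function(a) {
    i <- floor((tc[[a]] - mask$origin[a]) / mask$spacing[a]) + 1L
    i[i < 1L | i > src_dim[a]] <- NA_integer_
    as.integer(i)
  })
  if (all(is.na(idx[[1]])) || all(is.na(idx[[2]])) || all(is.na(idx[[3]])))
    stop("grids have disjoint physical extents")
  td <- dim(target$values)
  ii <- idx[[1]][slice.index(array(0L, td), 1)]
  jj <- idx[[2]][slice.index(array(0L, td), 2)]
  kk <- idx[[3]][slice.index(array(0L, td), 3)]
  inside <- !is.na(ii) & !is.na(jj) & !is.na(kk)
  vox <- array(FALSE, td)
  lin <- (as.numeric(kk[inside]) - 1) * src_dim[1] * src_dim[2] +
    (as.numeric(jj[inside]) - 1) * src_dim[1] + as.numeric(ii[inside])
  vox[inside] <- mask$voxels[lin]
  structure_mask(vox, target, allow_empty = TRUE)
}
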