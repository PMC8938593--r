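# small grids and masks built in code, shared across test files

make_grid <- function(dims = c(12, 12, 8), spacing = c(1, 1, 1),
                      values = NULL, unit = "HU", origin = NULL) {
  if (is.null(values)) values <- array(0, dims)
  voxel_grid(values, spacing = spacing, origin = origin, unit = unit)
}

make_ball_mask <- function(grid, center_mm = c(0, 0, 0), radius_mm = 3) {
  cc <- voxel_centers(grid)
  d2 <- outer(outer((cc[[1]] - center_mm[1])^2, (cc[[2]] - center_mm[2])^2, `+`),
              (cc[[3]] - center_mm[3])^2, `+`)
  structure_mask(d2 <= radius_mm^2, grid)
}

make_cyl_mask <- function(grid, center_mm = c(0, 0), radius_mm = 3,
                          half_length_mm = Inf) {
  cc <- voxel_centers(grid)
  d2 <- outer((cc[[1]] - center_mm[1])^2, (cc[[2]] - center_mm[2])^2, `+`)
  vox <- array(FALSE, dim(grid$values))
  for (k in seq_along(cc[[3]]))
    if (abs(cc[[3]][k]) <= half_length_mm) vox[, , k] <- d2 <= radius_mm^2
  structure_mask(vox, grid)
}

# brute-force physical-distance mask expansion (oracle for expand_mask)
expand_mask_bruteforce <- function(mask, margin) {
  cc <- voxel_centers(mask)
  d <- dim(mask$voxels)
  pts <- which(mask$voxels, arr.ind = TRUE)
  src <- cbind(cc[[1]][pts[, 1]], cc[[2]][pts[, 2]], cc[[3]][pts[, 3]])
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dd <- sqrt((src[, 1] - cc[[1]][i])^2 + (src[, 2] - cc[[2]][j])^2 +
                 (src[, 3] - cc[[3]][k])^2)
    out[i, j, k] <- any(dd <= margin + 1e-9)
  }
  out
}

# a small, fast phantom variant for unit tests (3 ring positions, one z
# extent); full default geometry is exercised in the acceptance tests
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(post_diameters = c(2, 9, 15), concentrations = c(0.5, 5, 25),
         post_axis_radius = 40, background_radius = 60,
         spacing = c(0.5, 0.5, 2)),
    list(...))
  do.call(phantom_spec, args)
}
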