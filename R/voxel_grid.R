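#' 3-D voxel grids with physical spacing and a unit tag
#'
#' A `VoxelGrid` is a 3-D numeric lattice together with its physical voxel
#' spacing (mm), the world coordinate of the first voxel's corner (mm), and
#' a unit tag recording what the values mean (`"HU"`, `"Bq"`, `"Bq/mL"`,
#' `"Gy"`, `"mg/mL"` or `"Gy/history"`). Voxel centres sit at
#' `origin + (i + 0.5) * spacing` along each axis (0-based `i`), so all
#' geometric operations work in millimetres rather than voxel counts.
#'
#' @param values numeric 3-D array of finite values.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the corner of the
#'   first voxel. Defaults to the grid being centred on the world origin.
#' @param unit unit tag string.
#' @return An object of class `VoxelGrid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 2), unit = "HU")
#' voxel_volume_ml(g)
#' @export
voxel_grid <- function(values, spacing, origin = NULL,
                       unit = c("HU", "Bq", "Bq/mL", "Gy", "mg/mL",
                                "Gy/history", "decays")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  if (any(!is.finite(values)))
    stop("`values` must be finite everywhere")
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  cat(sprintf("<VoxelGrid %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$unit, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.VoxelGrid <- function(x) dim(x$values)

#' Voxel volume of a grid in millilitres
#'
#' @param grid a [voxel_grid()].
#' @return Scalar voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

#' Voxel-centre world coordinates along each axis
#'
#' @param grid a [voxel_grid()] or [structure_mask()] reference grid.
#' @return List of three numeric vectors (mm).
#' @export
voxel_centers <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 0.5) * grid$spacing[a])
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Boolean structure masks bound to a reference grid
#'
#' A `StructureMask` stores a 3-D logical lattice on the same geometry as
#' the `VoxelGrid` it indexes (liver `L`, extended liver `L_shell`,
#' background `L_bkg`, body `B`, phantom posts, ...). Masks drawn on one
#' grid are moved to another only through [resample_mask()].
#'
#' @param voxels logical 3-D array.
#' @param reference the [voxel_grid()] the mask indexes.
#' @param allow_empty permit an all-`FALSE` mask.
#' @return An object of class `StructureMask`.
#' @export
structure_mask <- function(voxels, reference, allow_empty = FALSE) {
  if (!inherits(reference, "VoxelGrid")) stop("`reference` must be a VoxelGrid")
  if (is.numeric(voxels)) voxels <- array(voxels != 0, dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3-D logical array")
  if (!identical(dim(voxels), dim(reference$values)))
    stop("mask shape does not match its reference grid")
  if (!allow_empty && !any(voxels))
    stop("mask is empty")
  structure(list(voxels = voxels, spacing = reference$spacing,
                 origin = reference$origin,
                 values = voxels),  # `values` kept so geometry helpers apply
            class = "StructureMask")
}

#' @export
print.StructureMask <- function(x, ...) {
  cat(sprintf("<StructureMask> %s voxels, %d set (%.2f mL)\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              mask_volume_ml(x)))
  invisible(x)
}

#' Physical volume of a mask in millilitres
#' @param mask a [structure_mask()].
#' @return Volume in mL.
#' @export
mask_volume_ml <- function(mask) sum(mask$voxels) * prod(mask$spacing) / 1000

#' Summary statistics of grid values inside a mask
#'
#' Returns the mean and the population standard deviation (divide by n) of
#' the voxel values under the mask, the convention used for voxel
#' populations throughout the package.
#'
#' @param grid a [voxel_grid()].
#' @param mask a [structure_mask()] on the same geometry.
#' @return List with `mu`, `sigma`, `n_voxels`.
#' @export
mask_stats <- function(grid, mask) {
  stopifnot(inherits(grid, "VoxelGrid"), inherits(mask, "StructureMask"))
  if (!same_geometry(grid, mask))
    stop("mask and grid geometries differ")
  v <- grid$values[mask$voxels]
  n <- length(v)
  if (n == 0L) stop("mask is empty")
  mu <- mean(v)
  sigma <- sqrt(sum((v - mu)^2) / n)
  list(mu = mu, sigma = sigma, n_voxels = n)
}
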