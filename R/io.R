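#' Read a 3-D volume from NIfTI or MetaImage
#'
#' Spacing and origin are taken from the file header; the unit tag is
#' attached from the argument since neither format carries one. NIfTI
#' stores the world position of the first voxel *centre*; internally the
#' origin is the corner of the first voxel, and the conversion is handled
#' here.
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @param expected_unit unit tag to attach (see [voxel_grid()]).
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, expected_unit = "HU") {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha|\\.mhd)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    a <- array(as.vector(a), dim(a))  # plain array, no image attributes
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
    if (length(dim(a)) != 3L) stop("non-3-D data in '", path, "'")
    sp <- as.numeric(abs(RNifti::pixdim(img))[1:3])
    xf <- RNifti::xform(img)
    center0 <- xf[1:3, 4]
    # our files are written with a positive diagonal xform; take the
    # translation as the centre of voxel (0,0,0)
    orig <- as.numeric(center0) - 0.5 * sp * sign(diag(xf[1:3, 1:3]))
    orig <- ifelse(diag(xf[1:3, 1:3]) < 0, -(as.numeric(center0) + 0.5 * sp), orig)
    voxel_grid(a, spacing = sp, origin = orig, unit = expected_unit)
  } else if (ext %in% c(".mha", ".mhd")) {
    read_metaimage(path, expected_unit)
  } else stop("unsupported volume format: '", path, "'")
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param grid a [voxel_grid()] or [structure_mask()] (masks are written as
#'   8-bit 0/1).
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  is_mask <- inherits(grid, "StructureMask")
  vals <- if (is_mask) array(as.integer(grid$voxels), dim(grid$voxels)) else grid$values
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha|\\.mhd)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- grid$spacing
    m <- diag(c(grid$spacing, 1))
    m[1:3, 4] <- grid$origin + 0.5 * grid$spacing
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "double")
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(vals, grid$spacing, grid$origin, path,
                    type = if (is_mask) "MET_UCHAR" else "MET_DOUBLE")
  } else stop("unsupported volume format: '", path, "'")
  invisible(path)
}

# -- MetaImage (uncompressed) --------------------------------------------

meta_type <- function(type) {
  switch(type,
         MET_DOUBLE = list(what = "double", size = 8L),
         MET_FLOAT = list(what = "double", size = 4L),
         MET_UCHAR = list(what = "integer", size = 1L),
         MET_CHAR = list(what = "integer", size = 1L),
         MET_SHORT = list(what = "integer", size = 2L),
         MET_USHORT = list(what = "integer", size = 2L),
         MET_INT = list(what = "integer", size = 4L),
         stop("unsupported MetaImage ElementType: ", type))
}

read_metaimage <- function(path, expected_unit) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header in '", path, "'")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage is not supported")
  nd <- as.integer(hdr$NDims %||% "3")
  if (nd != 3L) stop("non-3-D data in '", path, "'")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  if (any(sp <= 0)) stop("non-positive spacing in '", path, "'")
  off <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  ty <- meta_type(hdr$ElementType %||% "MET_DOUBLE")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, ty$what, n = n, size = ty$size, endian = "little")
  } else {
    dpath <- file.path(dirname(path), hdr$ElementDataFile)
    raw <- readBin(dpath, ty$what, n = n, size = ty$size, endian = "little")
  }
  if (length(raw) != n) stop("raw block shorter than DimSize in '", path, "'")
  # MetaImage Offset is the centre of the first voxel
  voxel_grid(array(as.numeric(raw), dims), spacing = sp,
             origin = off - 0.5 * sp, unit = expected_unit)
}

write_metaimage <- function(vals, spacing, origin, path, type = "MET_DOUBLE") {
  ty <- meta_type(type)
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(dim(vals), collapse = " ")),
           paste("ElementSpacing =", paste(spacing, collapse = " ")),
           paste("Offset =", paste(origin + 0.5 * spacing, collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  dat <- if (ty$what == "integer") as.integer(vals) else as.numeric(vals)
  if (local) {
    writeBin(dat, con, size = ty$size, endian = "little")
    close(con)
  } else {
    close(con)
    writeBin(dat, file.path(dirname(path), datafile), size = ty$size,
             endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- structure sets -------------------------------------------------------

#' Write a named set of masks with a JSON sidecar
#'
#' Each mask is written as an 8-bit NIfTI volume and the sidecar records
#' the role (`L`, `L_shell`, `L_bkg`, `B`, ...) of each file.
#'
#' @param masks named list of [structure_mask()]s.
#' @param dir output directory.
#' @param sidecar sidecar file name.
#' @return Path of the sidecar, invisibly.
#' @export
write_structure_set <- function(masks, dir, sidecar = "structures.json") {
  stopifnot(is.list(masks), !is.null(names(masks)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- setNames(paste0(names(masks), ".nii.gz"), names(masks))
  for (role in names(masks)) write_volume(masks[[role]], file.path(dir, files[[role]]))
  jsonlite::write_json(as.list(files), file.path(dir, sidecar), auto_unbox = TRUE)
  invisible(file.path(dir, sidecar))
}

#' Read a structure set written by [write_structure_set()]
#'
#' @param sidecar path to the JSON sidecar.
#' @param reference the [voxel_grid()] the masks index.
#' @return Named list of [structure_mask()]s.
#' @export
read_structure_set <- function(sidecar, reference) {
  files <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out <- lapply(files, function(f) {
    g <- read_volume(file.path(dirname(sidecar), f), expected_unit = "HU")
    if (!all(abs(g$spacing - reference$spacing) < 1e-4))
      stop("mask spacing does not match the reference grid")
    structure_mask(g$values != 0, reference, allow_empty = TRUE)
  })
  out
}
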