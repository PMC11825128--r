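#' Construct a masked volume
#'
#' A `masked_volume` bundles a 3D intensity grid with a same-shaped boolean
#' mask of the structure of interest and the physical voxel size. Every
#' downstream stage (feature extraction, embedding, spatial statistics)
#' indexes into the masked voxels of this object, in the fixed order given by
#' [voxel_table()].
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param mask 3D array of the same shape; nonzero entries mark structure
#'   voxels and are binarized to logical.
#' @param voxel_size_um physical voxel edge length in micrometres, length 1
#'   (isotropic) or 3.
#' @param axis_names character(3), anatomical labels of the three grid axes in
#'   dimension order. Defaults to medial-lateral, posterior-anterior,
#'   inferior-superior.
#' @param reference optional `niftiImage` carrying the on-disk header, kept so
#'   maps written with [write_scalar_map()] preserve the input geometry.
#' @return An object of class `masked_volume`.
#' @export
masked_volume <- function(data, mask, voxel_size_um,
                          axis_names = .default_axes, reference = NULL) {
  data <- as.array(data)
  mask <- as.array(mask)
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  if (!identical(dim(data), dim(mask))) {
    stop(sprintf("shape mismatch: data is %s but mask is %s",
                 paste(dim(data), collapse = "x"),
                 paste(dim(mask), collapse = "x")), call. = FALSE)
  }
  mask <- array(is.finite(mask) & mask != 0, dim(mask))  # NaN/NA = background
  if (!any(mask)) stop("mask contains no voxels", call. = FALSE)
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), 3L)
  if (any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be positive on all three axes", call. = FALSE)
  }
  stopifnot(length(axis_names) == 3L)
  structure(
    list(data = data, mask = mask, voxel_size_um = voxel_size_um,
         axis_names = as.character(axis_names), reference = reference),
    class = "masked_volume"
  )
}

#' @exportS3Method base::print
print.masked_volume <- function(x, ...) {
  cat("<masked_volume> ", paste(dim(x$data), collapse = " x "),
      " grid, ", sum(x$mask), " masked voxels, voxel size ",
      paste(x$voxel_size_um, collapse = "/"), " um\n", sep = "")
  invisible(x)
}

# spatial unit code from the low 3 bits of xyzt_units; returns the factor
# that converts header pixdim to micrometres (unknown units treated as mm,
# the NIfTI convention)
.nifti_um_factor <- function(hdr) {
  unit <- bitwAnd(as.integer(hdr$xyzt_units), 7L)
  switch(as.character(unit), "1" = 1e6, "2" = 1e3, "3" = 1, 1e3)
}

.check_axis_aligned <- function(img, path) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error")) return(invisible())
  rot <- abs(xf[1:3, 1:3])
  scale <- pmax(apply(rot, 2, max), .Machine$double.eps)
  off <- sweep(rot, 2, scale, "/")
  diag(off) <- 0
  if (any(off > 1e-3)) {
    stop("volume '", path, "' has an oblique affine; subtexmap requires ",
         "axis-aligned grids (resample the image first)", call. = FALSE)
  }
  invisible()
}

#' Load an intensity volume and its structure mask
#'
#' Reads two NIfTI volumes of identical shape, binarizes the mask (any
#' nonzero value becomes true) and reads the voxel size from the image
#' header, converting header units to micrometres. Oblique affines are
#' rejected: all geometry here is axis-aligned scaling of grid indices.
#'
#' @param volume_path path to the intensity volume (.nii or .nii.gz).
#' @param mask_path path to the mask volume, same grid.
#' @param axis_names anatomical labels for the three grid axes.
#' @return A [masked_volume()].
#' @export
load_masked_volume <- function(volume_path, mask_path,
                               axis_names = .default_axes) {
  img <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (length(di) == 4L && di[4] == 1L) { dim(img) <- di <- di[1:3] }
  if (length(dm) == 4L && dm[4] == 1L) { dim(msk) <- dm <- dm[1:3] }
  if (length(di) != 3L) stop("volume is not 3D: ", volume_path, call. = FALSE)
  if (!identical(di, dm)) {
    stop(sprintf("shape mismatch: volume %s is %s but mask %s is %s",
                 volume_path, paste(di, collapse = "x"),
                 mask_path, paste(dm, collapse = "x")), call. = FALSE)
  }
  .check_axis_aligned(img, volume_path)
  hdr <- RNifti::niftiHeader(img)
  vox_um <- abs(as.numeric(hdr$pixdim[2:4])) * .nifti_um_factor(hdr)
  masked_volume(as.array(img), as.array(msk) != 0, vox_um,
                axis_names = axis_names, reference = img)
}

#' Voxel coordinate table of a masked volume
#'
#' One row per masked voxel, in a fixed deterministic order (the grid's
#' native linear order, first axis fastest) that every other stage of the
#' pipeline shares. Grid indices are 0-based; physical coordinates are the
#' indices scaled by the voxel size.
#'
#' @param volume a [masked_volume()].
#' @return A data.frame with columns `index` (1..n), `i`, `j`, `k` (0-based
#'   grid indices) and `x_um`, `y_um`, `z_um`; the anatomical axis names are
#'   attached as attribute `axis_names`.
#' @export
voxel_table <- function(volume) {
  stopifnot(inherits(volume, "masked_volume"))
  lin <- which(volume$mask)
  ijk <- arrayInd(lin, dim(volume$mask)) - 1L
  tab <- data.frame(
    index = seq_along(lin),
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x_um = ijk[, 1] * volume$voxel_size_um[1],
    y_um = ijk[, 2] * volume$voxel_size_um[2],
    z_um = ijk[, 3] * volume$voxel_size_um[3]
  )
  attr(tab, "axis_names") <- volume$axis_names
  attr(tab, "linear_index") <- lin
  tab
}

#' Physical coordinate along a named anatomical axis
#'
#' @param table a [voxel_table()].
#' @param axis one of the table's axis names.
#' @return numeric vector of coordinates (um), one per masked voxel.
#' @export
axis_coordinate <- function(table, axis) {
  axes <- attr(table, "axis_names")
  if (is.null(axes)) axes <- .default_axes
  idx <- .match_axis(axis, axes)
  table[[c("x_um", "y_um", "z_um")[idx]]]
}

#' Write a per-voxel scalar map back into the volume grid
#'
#' Scatters one value per masked voxel into the 3D grid (in [voxel_table()]
#' order) and writes a NIfTI volume with the input's header geometry.
#' Background voxels are written as NaN, never 0, so downstream tools cannot
#' mistake background for a valid low value.
#'
#' @param values numeric vector, one value per masked voxel.
#' @param volume the [masked_volume()] the values are defined on.
#' @param path output file path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(values, volume, path) {
  stopifnot(inherits(volume, "masked_volume"))
  n <- sum(volume$mask)
  if (length(values) != n) {
    stop(sprintf("values has length %d but the mask has %d voxels",
                 length(values), n), call. = FALSE)
  }
  grid <- array(NaN, dim(volume$mask))
  grid[volume$mask] <- as.numeric(values)
  img <- if (!is.null(volume$reference)) {
    RNifti::asNifti(grid, reference = volume$reference, datatype = "double")
  } else {
    # mm-unit header carrying the voxel size
    attr(grid, "pixdim") <- volume$voxel_size_um / 1e3
    RNifti::asNifti(grid, datatype = "double")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Gather a scalar map from a written volume back to voxel order
#'
#' Inverse of [write_scalar_map()]: reads a NIfTI volume and returns the
#' values at the masked voxels, in [voxel_table()] order.
#'
#' @inheritParams write_scalar_map
#' @param path path to a volume on the same grid.
#' @return numeric vector of length `sum(volume$mask)`.
#' @export
read_scalar_map <- function(path, volume) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (!identical(dim(arr), dim(volume$mask))) {
    stop("map grid does not match the volume grid", call. = FALSE)
  }
  arr[volume$mask]
}
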