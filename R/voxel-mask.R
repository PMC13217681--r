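#' Binary occupancy mask on a regular anisotropic voxel grid
#'
#' The basic spatial container of the package: a 3D logical lattice together
#' with the physical voxel size per axis (mm) and the physical coordinate of
#' the centre of voxel `[1, 1, 1]`. It represents a delineated structure
#' (e.g. an observer's or the reference clinical target volume) rasterised on
#' the planning grid. All geometric metrics operate on pairs of masks that
#' share the same grid (shape, spacing and origin); no resampling is ever
#' performed.
#'
#' @param occupancy A 3D `logical` (or coercible numeric) array; any non-zero
#'   value counts as foreground.
#' @param spacing Numeric length-3, physical voxel size along each array axis
#'   in mm; all components must be strictly positive.
#' @param origin Numeric length-3, physical coordinate (mm) of the centre of
#'   the first voxel.
#' @return An object of class `voxel_mask`.
#' @examples
#' m <- voxel_mask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' mask_volume(m) # 1 cm^3
#' @export
voxel_mask <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    err_invalid_geometry("occupancy must be a 3D array")
  if (!is.logical(occupancy)) {
    occ <- array(as.logical(occupancy != 0), dim = dim(occupancy))
  } else {
    occ <- occupancy
  }
  if (anyNA(occ)) err_invalid_geometry("occupancy contains missing values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    err_invalid_geometry("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || anyNA(origin))
    err_invalid_geometry("origin must be three finite values (mm)")
  structure(list(occupancy = occ, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<voxel_mask> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d foreground (%.2f cm^3)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$occupancy), mask_volume(x)))
  invisible(x)
}

#' @rdname voxel_mask
#' @param x Object to test.
#' @export
is_voxel_mask <- function(x) inherits(x, "voxel_mask")

assert_mask <- function(x, arg = "mask") {
  if (!is_voxel_mask(x))
    err_invalid_parameter(sprintf("%s is not a voxel_mask", arg))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$occupancy)

# shared-grid contract: identical shape, spacing and origin (no resampling)
assert_same_grid <- function(a, b) {
  if (!identical(dim(a$occupancy), dim(b$occupancy)))
    err_invalid_geometry("masks do not share the same grid shape")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    err_invalid_geometry("masks do not share the same voxel spacing")
  if (max(abs(a$origin - b$origin)) > 1e-6)
    err_invalid_geometry("masks do not share the same grid origin")
  invisible(TRUE)
}

# physical coordinates (mm) of foreground (or given) voxel centres, n x 3
voxel_coords <- function(mask, which_idx = NULL) {
  if (is.null(which_idx)) which_idx <- which(mask$occupancy)
  ijk <- arrayInd(which_idx, dim(mask$occupancy))
  sweep(sweep(ijk - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Physical volume of a mask
#'
#' Foreground voxel count times the voxel volume, reported in cm^3 (the unit
#' clinical structure volumes are reported in). An empty mask has volume 0.
#'
#' @param mask A [voxel_mask].
#' @return Volume in cm^3.
#' @export
mask_volume <- function(mask) {
  assert_mask(mask)
  sum(mask$occupancy) * prod(mask$spacing) / 1000
}

#' Read a binary mask from a NIfTI file
#'
#' Any non-zero voxel is treated as foreground. Spacing is taken from the
#' header; the stored orientation must be axis-aligned (scaling and axis sign
#' flips are accepted, rotations are rejected — resampling is out of scope).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_mask].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) err_io(sprintf("mask file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) err_io(sprintf("cannot read %s: %s", path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    err_invalid_geometry(sprintf("%s is not a 3D volume", path))
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  scale <- sqrt(colSums(rot^2))
  if (any(scale <= 0)) err_invalid_geometry(sprintf("%s has degenerate voxel spacing", path))
  offdiag <- abs(rot) - diag(abs(diag(rot)))
  if (max(abs(offdiag)) > 1e-4 * max(scale))
    err_invalid_geometry(sprintf("%s: oblique/rotated orientation not supported (axis-aligned only)", path))
  voxel_mask(arr != 0, spacing = abs(diag(rot)), origin = xf[1:3, 4])
}

#' Write a mask to a NIfTI file
#'
#' Foreground is stored as 1, background as 0, with the grid spacing and
#' origin recorded in an axis-aligned sform.
#'
#' @param mask A [voxel_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  arr <- array(as.integer(mask$occupancy), dim = dim(mask$occupancy))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  aff <- diag(c(mask$spacing, 1))
  aff[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# squared anisotropic EDT (mm^2) to the centres of `seed` voxels
edt_sq <- function(seed, spacing) {
  as.numeric(.edt_squared(as.logical(seed), as.integer(dim(seed)), as.numeric(spacing)))
}

# squared anisotropic distance (mm^2) to the nearest seed-voxel box;
# values beyond `cap` mm are upper bounds only
region_dt_sq <- function(seed, spacing, cap = Inf) {
  as.numeric(.region_dt_squared(as.logical(seed), as.integer(dim(seed)),
                                as.numeric(spacing), as.numeric(cap)))
}
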