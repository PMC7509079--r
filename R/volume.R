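#' Image volume container
#'
#' A minimal 3-D image container: an intensity array plus isotropic-or-not
#' voxel spacing in millimetres. World coordinates are
#' `(index - 1) * spacing` on each axis (axis-aligned, origin at the first
#' voxel centre), which is the convention used throughout the package; the
#' NIfTI reader/writer maps the pixdim fields onto `spacing`.
#'
#' @param data Numeric 3-D array of intensities.
#' @param spacing Numeric length-3 voxel spacing in mm (all > 0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_input("image_volume: data must be a 3-D array, got %d dims",
               length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("image_volume: spacing must be 3 positive numbers")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Cord mask container
#'
#' A probabilistic (0-1) cord segmentation on the same grid as an
#' [image_volume()]. Axial slices are indexed along the third axis, which is
#' the (approximate) cord axis.
#'
#' @param data Numeric 3-D array with values in \[0, 1\].
#' @param spacing Voxel spacing in mm.
#' @return An object of class `cord_mask` (also an `image_volume`).
#' @export
cord_mask <- function(data, spacing = c(1, 1, 1)) {
  vol <- image_volume(data, spacing)
  rng <- range(vol$data)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    stop_input("cord_mask: probabilities must lie in [0, 1] (range %.3g..%.3g)",
               rng[1], rng[2])
  vol$data <- clamp(vol$data, 0, 1)
  class(vol) <- c("cord_mask", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param vol An [image_volume()].
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Total (probabilistic) mask volume in cubic millimetres
#' @param mask A [cord_mask()].
#' @return Sum of mask probabilities times the voxel volume.
#' @export
mask_volume <- function(mask) sum(mask$data) * voxel_volume(mask)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask If `TRUE`, return a [cord_mask()] (values clamped to \[0,1\]).
#' @return An [image_volume()] or [cord_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  data <- array(as.numeric(img), dim = dim(img)[1:3])
  if (mask) cord_mask(clamp(data, 0, 1), spacing)
  else image_volume(data, spacing)
}

#' Write a NIfTI volume
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Continuous 0-based voxel coords of world-mm points (rows of `pts_mm`).
world_to_voxel <- function(pts_mm, spacing) {
  sweep(pts_mm, 2, spacing, "/")
}

voxel_to_world <- function(pts_vox, spacing) {
  sweep(pts_vox, 2, spacing, "*")
}

# Trilinear interpolation of an image_volume at world-mm points.
interp_world <- function(vol, pts_mm, fill = 0) {
  pts <- world_to_voxel(pts_mm, vol$spacing)
  .interp_trilinear(as.numeric(vol$data), dim(vol$data), pts, fill)
}
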