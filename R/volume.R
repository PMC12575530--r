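#' @useDynLib dpdetect, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' 3-D image volume with physical spacing
#'
#' Lightweight carrier for masks and heatmaps: a 3-D array on a regular
#' voxel grid with physical spacing in millimetres. Axis orientation is
#' assumed identity (i, j, k increase along +x, +y, +z); voxel centre
#' `(i, j, k)` (1-indexed) sits at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3-D array (logical or numeric).
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' Convert voxel indices to world coordinates (mm)
#'
#' @param vol an [image_volume].
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' Convert world coordinates (mm) to nearest voxel indices
#'
#' @param vol an [image_volume].
#' @param xyz numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return integer matrix (n x 3) of 1-based voxel indices (may fall
#'   outside the grid; callers must bounds-check).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ijk <- sweep(sweep(xyz, 2L, vol$origin, "-"), 2L, vol$spacing, "/") + 1
  matrix(as.integer(round(ijk)), ncol = 3L)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param logical coerce voxel values to logical (for masks).
#' @return An [image_volume]; spacing is taken from the NIfTI pixdim.
#' @export
read_volume <- function(path, logical = FALSE) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  arr <- array(as.vector(img), dim = dim(img)[seq_len(3L)])
  if (logical) arr <- arr > 0.5
  image_volume(arr, spacing)
}

#' Write a volume as NIfTI
#'
#' Masks are written as 0/1; spacing is stored in the NIfTI pixdim.
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- vol$data
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# largest 26-connected component of a logical array
largest_component <- function(arr) {
  labels <- .cc_label_3d(as.logical(arr), dim(arr), 26L)
  if (all(labels == 0L)) stop("mask is empty: no foreground voxels")
  tab <- tabulate(labels)
  keep <- which.max(tab)
  array(labels == keep, dim = dim(arr))
}
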