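#' Image stack container
#'
#' A 3D grayscale volume with its physical voxel size. Values are raw 16-bit
#' grayscale units (0--65535) stored as doubles; the array is indexed
#' `[row, col, slice]` with isotropic in-plane voxels of side `voxel_side`
#' micrometres. The slab thickness is `n_slices x voxel_side`.
#'
#' @param voxels numeric 3D array `[row, col, slice]` (a matrix is promoted
#'   to a single-slice stack).
#' @param voxel_side voxel side in micrometres (default 47.7, the acquisition
#'   geometry the package targets).
#' @return An object of class `image_stack` with fields `voxels`,
#'   `voxel_side`, `n_slices`.
#' @export
image_stack <- function(voxels, voxel_side = 47.7) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L) stopf("voxels must be a [row, col, slice] array")
  if (!is.numeric(voxel_side) || length(voxel_side) != 1L || voxel_side <= 0)
    stopf("voxel_side must be a single positive length (um)")
  structure(
    list(voxels = voxels, voxel_side = voxel_side, n_slices = dim(voxels)[3L]),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d pixels, %d slice(s), voxel %.4g um, slab %.4g mm\n",
              d[1], d[2], d[3], x$voxel_side, slab_thickness_mm(d[3], x$voxel_side)))
  invisible(x)
}

#' Parenchyma mask container
#'
#' Holds the analyzed parenchyma (`included`) and the non-ventilated
#' (flooded/atelectatic) regions removed from analysis
#' (`excluded_nonventilated`). The two are disjoint by construction; their
#' union is the full parenchyma outline used for pleural-distance
#' computation.
#'
#' @param included logical 3D array of analyzed parenchyma voxels.
#' @param excluded_nonventilated logical 3D array of excluded non-ventilated
#'   voxels (default: none).
#' @param voxel_side voxel side in micrometres.
#' @return An object of class `parenchyma_mask`.
#' @export
parenchyma_mask <- function(included, excluded_nonventilated = NULL, voxel_side = 47.7) {
  if (is.matrix(included)) included <- array(included, dim = c(dim(included), 1L))
  if (is.null(excluded_nonventilated))
    excluded_nonventilated <- array(FALSE, dim = dim(included))
  if (is.matrix(excluded_nonventilated))
    excluded_nonventilated <- array(excluded_nonventilated, dim = c(dim(excluded_nonventilated), 1L))
  if (!identical(dim(included), dim(excluded_nonventilated)))
    stopf("included and excluded_nonventilated dimensions differ")
  if (any(included & excluded_nonventilated))
    stopf("included and excluded_nonventilated overlap")
  structure(
    list(included = included,
         excluded_nonventilated = excluded_nonventilated,
         voxel_side = voxel_side),
    class = "parenchyma_mask"
  )
}

#' @export
print.parenchyma_mask <- function(x, ...) {
  cat(sprintf("parenchyma_mask: %d analyzed voxels, %d excluded non-ventilated, %d slice(s)\n",
              sum(x$included), sum(x$excluded_nonventilated), dim(x$included)[3]))
  invisible(x)
}

#' Slab thickness covered by a stack
#'
#' @param n_slices number of contiguous slices.
#' @param voxel_side voxel side in micrometres.
#' @return Thickness in millimetres (e.g. 40 slices at 47.7 um = 1.908 mm).
#' @export
slab_thickness_mm <- function(n_slices, voxel_side = 47.7) {
  n_slices * voxel_side / 1000
}
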