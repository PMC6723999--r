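#' Pleural distance map
#'
#' Per-slice 2D Euclidean distance (in micrometres) from each voxel of the
#' parenchyma to the nearest voxel outside the full parenchyma outline.
#' Excluded non-ventilated regions count as interior for the outline (they
#' sit on the pleural perimeter and must not create an artificial pleural
#' surface inside the lung). The convention is distance between voxel
#' centers: a voxel on the pleural boundary has distance `voxel_side`, and
#' the distance is nowhere 0 inside the outline.
#'
#' @param mask a [parenchyma_mask()].
#' @return A list of class `pleural_distance` with `distance` (array, um),
#'   `voxel_side`, and `empty_slices` (indices of slices with an empty mask,
#'   flagged and left at distance 0).
#' @export
pleural_distance_map <- function(mask) {
  stopifnot(inherits(mask, "parenchyma_mask"))
  outline <- mask$included | mask$excluded_nonventilated
  dm <- dim(outline)
  d <- array(0, dim = dm)
  empty <- integer(0)
  for (s in seq_len(dm[3])) {
    if (!any(outline[, , s])) { empty <- c(empty, s); next }
    d[, , s] <- as.matrix(EBImage::distmap(outline[, , s])) * mask$voxel_side
  }
  structure(list(distance = d, voxel_side = mask$voxel_side,
                 empty_slices = empty),
            class = "pleural_distance")
}

#' Partition the analyzed parenchyma into concentric pleural-distance bands
#'
#' Three contiguous bands tile the analyzed mask by distance from the
#' pleural surface: subpleural `[o1, o2)`, mantellar `[o2, o3)`, and core
#' `[o3, Inf)` (half-open intervals, offsets in mm, default 0/2/4 mm). Every
#' analyzed voxel belongs to exactly one band.
#'
#' @param distance a [pleural_distance_map()] result.
#' @param offsets strictly ascending band inner edges in mm; the first must
#'   be 0.
#' @param mask the [parenchyma_mask()] whose `included` voxels are
#'   partitioned (excluded regions get no band).
#' @return An object of class `roi_partition` with `band` (integer array:
#'   0 = none, 1 = SUB, 2 = MAN, 3 = COR), `band_names`, `offsets`,
#'   `voxel_side`.
#' @export
partition_rois <- function(distance, offsets = c(0, 2, 4), mask) {
  stopifnot(inherits(distance, "pleural_distance"),
            inherits(mask, "parenchyma_mask"))
  if (length(offsets) != 3 || is.unsorted(offsets, strictly = TRUE))
    stopf("offsets must be three strictly ascending values (mm)")
  if (offsets[1] != 0) stopf("the first offset must be 0 mm")
  band <- array(0L, dim = dim(distance$distance))
  d_mm <- distance$distance / 1000
  inc <- mask$included
  band[inc] <- findInterval(d_mm[inc], c(offsets, Inf),
                            rightmost.closed = FALSE)
  structure(list(band = band, band_names = c("SUB", "MAN", "COR"),
                 offsets = offsets, voxel_side = distance$voxel_side),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  tab <- tabulate(x$band[x$band > 0], nbins = 3)
  cat(sprintf("roi_partition at %s mm: SUB %d, MAN %d, COR %d voxels\n",
              paste(x$offsets, collapse = "/"), tab[1], tab[2], tab[3]))
  invisible(x)
}
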