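#' Exclude flooded/atelectatic regions from the analyzed parenchyma
#'
#' Non-ventilated (flooded or atelectatic) tissue appears as solid regions of
#' tissue-like density on the external perimeter of the parenchyma. What
#' distinguishes them from the septal network — which is also dense but
#' everywhere thin — is tissue depth: flooded regions contain voxels far from
#' any gas. Per slice, dense voxels (`>= density_threshold`) at Euclidean
#' distance `>= deep_radius` from the nearest gas voxel form candidate cores;
#' each core is recovered to its full dense extent by geodesic dilation and
#' hole-filled, and the region is moved to `excluded_nonventilated` when it
#' touches the mask perimeter, exceeds `min_region` voxels, and is at least
#' 90% dense. Interior dense regions (vessels, thick septa, local packing
#' vacancies) never touch the perimeter and are retained.
#'
#' @param image an [image_stack()].
#' @param mask a [parenchyma_mask()] aligned with `image`.
#' @param density_threshold grayscale value separating gas from tissue
#'   density; must lie within the image range.
#' @param min_region minimum excluded-region size (voxels).
#' @param deep_radius minimum tissue depth (voxels) identifying solid
#'   non-aerated regions. The default 20 voxels (about 950 um at 47.7 um
#'   voxels) is the scale of injury-caused flooded caps: well above septal
#'   half-widths and above the tissue pockets that transient physiological
#'   closure of scattered airspaces produces.
#' @param max_hole largest interior hole (voxels) filled when the region is
#'   recovered; larger gas pockets enclosed by the region stay analyzed.
#' @return The updated [parenchyma_mask()]; the analyzed volume shrinks by
#'   the excluded voxels.
#' @export
exclude_nonventilated <- function(image, mask, density_threshold,
                                  min_region = 50, deep_radius = 20,
                                  max_hole = 4) {
  stopifnot(inherits(image, "image_stack"), inherits(mask, "parenchyma_mask"))
  if (!identical(dim(image$voxels), dim(mask$included)))
    stopf("image and mask are not aligned")
  rng <- range(image$voxels)
  if (density_threshold < rng[1] || density_threshold > rng[2])
    stopf("density_threshold %.4g outside image range [%.4g, %.4g]",
          density_threshold, rng[1], rng[2])
  box3 <- EBImage::makeBrush(3, "box")
  included <- mask$included
  excluded <- mask$excluded_nonventilated
  for (s in seq_len(dim(included)[3])) {
    inc <- included[, , s]
    if (!any(inc)) next
    dense <- inc & image$voxels[, , s] >= density_threshold
    if (!any(dense)) next
    gas <- inc & !dense
    depth <- if (any(gas)) as.matrix(EBImage::distmap(!gas)) else
      matrix(Inf, nrow(inc), ncol(inc))
    core <- dense & depth >= deep_radius
    if (!any(core)) next
    # recover the shallow rim of each solid region, staying within dense
    blob <- core
    for (it in seq_len(deep_radius + 2))
      blob <- dense & as.matrix(EBImage::dilate(blob, box3)) > 0
    comps <- cpp_label8(blob)
    # mask voxels touching the exterior (the image border counts as exterior)
    perim <- shift_any4(!inc) & inc
    perim[c(1, nrow(inc)), ] <- inc[c(1, nrow(inc)), ]
    perim[, c(1, ncol(inc))] <- perim[, c(1, ncol(inc))] | inc[, c(1, ncol(inc))]
    for (k in seq_len(max(comps))) {
      sel <- comps == k
      # close small interior holes (noise speckles) but never swallow an
      # enclosed ventilated airspace
      filled <- as.matrix(EBImage::fillHull(sel)) > 0 & inc
      holes <- filled & !sel
      if (any(holes)) {
        hl <- cpp_label8(holes)
        big <- which(tabulate(hl[hl > 0]) > max_hole)
        filled[holes & hl %in% big] <- FALSE
      }
      if (sum(filled) <= min_region) next
      # a flooded/atelectatic region is deep right at the pleural surface;
      # deep interior pockets of the septal network never are
      if (!any(sel & core & perim)) next
      if (mean(dense[filled]) < 0.9) next
      included[, , s][filled] <- FALSE
      excluded[, , s][filled] <- TRUE
    }
  }
  parenchyma_mask(included, excluded, mask$voxel_side)
}

#' Multi-scale black top-hat airspace enhancement
#'
#' Gas-filled airspaces are dark structures on a bright tissue background;
#' the black top-hat (morphological closing minus the image) turns dark
#' structures up to the structuring-element diameter into positive peaks.
#' A ladder of disc radii is applied per slice and combined by voxelwise
#' maximum, so airspaces across the physiological size range respond at the
#' scale that matches them. The image is optionally Gaussian-smoothed first
#' (`smooth_sigma`) to stabilize peak detection under acquisition noise.
#'
#' @param image an [image_stack()] (raw grayscale).
#' @param mask a [parenchyma_mask()]; the enhanced image is 0 outside the
#'   analyzed mask.
#' @param radii ascending disc radii in voxels (each >= 1). The default
#'   ladder `c(2, 3, 4, 6)` brackets structuring-element diameters of about
#'   190--570 um at 47.7 um voxels, comfortably covering the ~110 um alveolar
#'   scale after phase-contrast blur.
#' @param smooth_sigma Gaussian pre-smoothing sd in voxels (0 disables).
#' @return An [image_stack()] of enhancement values (same grayscale units).
#' @export
tophat_enhance <- function(image, mask, radii = c(2, 3, 4, 6),
                           smooth_sigma = 0.8) {
  stopifnot(inherits(image, "image_stack"), inherits(mask, "parenchyma_mask"))
  if (length(radii) == 0) stopf("radii must be a non-empty ascending list")
  if (any(radii < 1)) stopf("all radii must be >= 1 voxel")
  if (is.unsorted(radii, strictly = TRUE)) stopf("radii must be ascending")
  if (!identical(dim(image$voxels), dim(mask$included)))
    stopf("image and mask are not aligned")
  brushes <- lapply(radii, disc_brush)
  out <- array(0, dim = dim(image$voxels))
  for (s in seq_len(dim(out)[3])) {
    inc <- mask$included[, , s]
    if (!any(inc)) next
    # the raw values outside the mask stay in place: the pleural/chest-wall
    # neighbourhood legitimately bounds subpleural airspaces, and replacing
    # it with a synthetic fill manufactures spurious boundary valleys
    x <- image$voxels[, , s]
    if (smooth_sigma > 0) x <- ebi_gblur(x, smooth_sigma)
    enh <- matrix(0, nrow(x), ncol(x))
    for (b in brushes) enh <- pmax(enh, as.matrix(ebi_closing(x, b)) - x)
    enh[!inc] <- 0
    out[, , s] <- pmax(enh, 0)
  }
  image_stack(out, image$voxel_side)
}

#' Count airspaces as local negative-intensity peaks
#'
#' Airspace number (NAs) per slice is the count of regional maxima of the
#' top-hat--enhanced image (i.e. negative intensity peaks of the original)
#' with prominence at least `h_depth`, computed by the h-maxima transform
#' (grayscale reconstruction by dilation). A connected plateau counts once,
#' at its centroid. Maxima closer than `min_separation` are merged, keeping
#' the highest (ties broken by lowest `(row, col)`). When the raw image and
#' a tissue threshold are supplied, peaks sitting at tissue density are
#' discarded: an airspace peak must be gas-dark in the original image.
#'
#' @param enhanced output of [tophat_enhance()].
#' @param mask a [parenchyma_mask()].
#' @param h_depth minimum peak prominence (grayscale units); must be > 0.
#'   Default: 5% of the dynamic range of the enhanced image inside the mask.
#' @param min_separation minimum peak separation in micrometres.
#' @param image,tissue_threshold optional raw image and density gate for the
#'   peaks (see above).
#' @return An object of class `airspace_labels` holding `peaks` (data frame:
#'   slice, row, col, value), `nas_per_slice`, and a `labels` slot (filled by
#'   [delineate_airspaces()]).
#' @export
count_airspaces <- function(enhanced, mask, h_depth = NULL,
                            min_separation = 110,
                            image = NULL, tissue_threshold = NULL) {
  stopifnot(inherits(enhanced, "image_stack"), inherits(mask, "parenchyma_mask"))
  inc_any <- mask$included
  if (is.null(h_depth)) {
    v <- enhanced$voxels[inc_any]
    # floor of one grayscale unit so a structureless (flat) enhanced image
    # yields zero peaks rather than an error
    h_depth <- max(1, 0.05 * (max(v) - min(v)))
  }
  if (h_depth <= 0) stopf("h_depth must be > 0")
  sep_vox <- min_separation / enhanced$voxel_side
  ns <- dim(enhanced$voxels)[3]
  peak_rows <- vector("list", ns)
  nas <- integer(ns)
  for (s in seq_len(ns)) {
    inc <- inc_any[, , s]
    if (!any(inc)) next
    e <- round(enhanced$voxels[, , s])
    e[!inc] <- 0
    h <- cpp_reconstruct_dilate(e - h_depth, e)
    rmax <- (h - cpp_reconstruct_dilate(h - 1, h)) >= 0.5
    rmax <- rmax & inc
    if (!any(rmax)) next
    comps <- cpp_label8(rmax)
    ncomp <- max(comps)
    idx <- which(comps > 0)
    ri <- ((idx - 1) %% nrow(e)) + 1
    ci <- ((idx - 1) %/% nrow(e)) + 1
    lab <- comps[idx]
    vmax <- vapply(split(e[idx], lab), max, numeric(1))
    keep_comp <- which(vmax >= h_depth)
    if (length(keep_comp) == 0) next
    pk <- do.call(rbind, lapply(keep_comp, function(k) {
      sel <- lab == k
      # plateau centroid, snapped to the nearest plateau pixel
      cr <- mean(ri[sel]); ccol <- mean(ci[sel])
      d2 <- (ri[sel] - cr)^2 + (ci[sel] - ccol)^2
      o <- order(d2, ri[sel], ci[sel])[1]
      c(ri[sel][o], ci[sel][o], vmax[k])
    }))
    pk <- data.frame(row = pk[, 1], col = pk[, 2], value = pk[, 3])
    if (!is.null(image) && !is.null(tissue_threshold)) {
      raw <- image$voxels[, , s]
      pk <- pk[raw[cbind(pk$row, pk$col)] < tissue_threshold, , drop = FALSE]
    }
    if (nrow(pk) > 1 && sep_vox > 0) {
      ord <- order(-pk$value, pk$row, pk$col)
      pk <- pk[ord, , drop = FALSE]
      keep <- logical(nrow(pk))
      for (i in seq_len(nrow(pk))) {
        if (!any(keep)) { keep[i] <- TRUE; next }
        d <- sqrt((pk$row[keep] - pk$row[i])^2 + (pk$col[keep] - pk$col[i])^2)
        if (all(d >= sep_vox)) keep[i] <- TRUE
      }
      pk <- pk[keep, , drop = FALSE]
    }
    pk <- pk[order(pk$row, pk$col), , drop = FALSE]
    if (nrow(pk)) {
      peak_rows[[s]] <- data.frame(slice = s, pk, row.names = NULL)
      nas[s] <- nrow(pk)
    }
  }
  peaks <- do.call(rbind, peak_rows)
  if (is.null(peaks))
    peaks <- data.frame(slice = integer(0), row = numeric(0),
                        col = numeric(0), value = numeric(0))
  structure(list(labels = NULL, peaks = peaks, nas_per_slice = nas,
                 voxel_side = enhanced$voxel_side, dropped_peaks = 0L),
            class = "airspace_labels")
}

#' Delineate airspaces around counted peaks
#'
#' Each peak seeds a region grown over gas-density voxels (below
#' `tissue_threshold`) inside the analyzed mask; contested voxels are
#' assigned by intensity-guided seeded propagation, so region boundaries
#' follow tissue-density ridges (the septal walls). Peaks that sit at or
#' above tissue density are dropped and counted in `dropped_peaks`. Labels
#' are dense `1..NAs` per slice, matching the order of the peak table.
#'
#' @param image the raw [image_stack()].
#' @param peaks an `airspace_labels` from [count_airspaces()] (or a data
#'   frame of slice/row/col peaks).
#' @param mask a [parenchyma_mask()].
#' @param tissue_threshold grayscale value separating gas from tissue.
#' @return An `airspace_labels` with the `labels` integer array filled,
#'   per-slice dense labels, updated `peaks` (with a `label` column and
#'   per-label `area`), `nas_per_slice`, and `dropped_peaks`.
#' @export
delineate_airspaces <- function(image, peaks, mask, tissue_threshold) {
  stopifnot(inherits(image, "image_stack"), inherits(mask, "parenchyma_mask"))
  pk <- if (inherits(peaks, "airspace_labels")) peaks$peaks else peaks
  dm <- dim(image$voxels)
  labels <- array(0L, dim = dm)
  ns <- dm[3]
  nas <- integer(ns)
  dropped <- 0L
  out_rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    inc <- mask$included[, , s]
    p <- pk[pk$slice == s, , drop = FALSE]
    if (nrow(p) == 0 || !any(inc)) next
    x <- image$voxels[, , s]
    gas <- inc & x < tissue_threshold
    at <- cbind(p$row, p$col)
    ok <- gas[at]
    dropped <- dropped + sum(!ok)
    p <- p[ok, , drop = FALSE]
    if (nrow(p) == 0) next
    p <- p[order(p$row, p$col), , drop = FALSE]
    seeds <- matrix(0L, dm[1], dm[2])
    seeds[cbind(p$row, p$col)] <- seq_len(nrow(p))
    lab <- as.matrix(EBImage::propagate(x / GRAY_MAX, seeds, mask = gas))
    storage.mode(lab) <- "integer"
    labels[, , s] <- lab
    nas[s] <- nrow(p)
    p$label <- seq_len(nrow(p))
    p$area <- as.integer(tabulate(lab[lab > 0], nbins = nrow(p)))
    out_rows[[s]] <- p
  }
  peaks_out <- do.call(rbind, out_rows)
  if (is.null(peaks_out))
    peaks_out <- data.frame(slice = integer(0), row = numeric(0),
                            col = numeric(0), value = numeric(0),
                            label = integer(0), area = integer(0))
  row.names(peaks_out) <- NULL
  structure(list(labels = labels, peaks = peaks_out, nas_per_slice = nas,
                 voxel_side = image$voxel_side, dropped_peaks = dropped),
            class = "airspace_labels")
}

#' @export
print.airspace_labels <- function(x, ...) {
  cat(sprintf("airspace_labels: %d peaks over %d slice(s)%s%s\n",
              nrow(x$peaks), length(x$nas_per_slice),
              if (is.null(x$labels)) " (not delineated)" else "",
              if (x$dropped_peaks > 0)
                sprintf(", %d peak(s) dropped at tissue density", x$dropped_peaks)
              else ""))
  invisible(x)
}
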