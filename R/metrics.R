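#' Analyzed volume of a region of interest on one slice
#'
#' The volume subtended by a ROI on a slice is the analyzed voxel count
#' times the voxel volume (each voxel is a cube of side `voxel_side`),
#' reported in cubic millimetres.
#'
#' @param mask a [parenchyma_mask()].
#' @param partition a [partition_rois()] result.
#' @param roi `"ALL"`, `"SUB"`, `"MAN"` or `"COR"`.
#' @param slice_index slice number.
#' @return Volume in mm^3 (0 for an empty ROI; downstream ASnum is then
#'   flagged missing).
#' @export
roi_volume <- function(mask, partition, roi = c("ALL", "SUB", "MAN", "COR"),
                       slice_index) {
  stopifnot(inherits(mask, "parenchyma_mask"), inherits(partition, "roi_partition"))
  roi <- match.arg(roi)
  n <- if (roi == "ALL") sum(mask$included[, , slice_index])
       else sum(partition$band[, , slice_index] == match(roi, partition$band_names))
  n * (mask$voxel_side / 1000)^3
}

#' Compute per-slice, per-ROI airspace metrics
#'
#' For each slice and each ROI (the entire slice plus the three concentric
#' bands): `NAs` is the number of airspaces whose peak lies in the ROI;
#' `gas_area` is the labeled gas area (voxels) falling inside the ROI (an
#' airspace straddling two bands is counted once, in its peak's band, while
#' its area contributes to each band it overlaps, keeping NAs additive and
#' area conservative); `ASnum = NAs / analyzed_volume` (units/mm^3);
#' `ASdim = gas_area / NAs` (voxels), missing when `NAs = 0`.
#'
#' @param labelmap a delineated `airspace_labels` (see
#'   [delineate_airspaces()]).
#' @param partition a [partition_rois()] result.
#' @param mask a [parenchyma_mask()].
#' @param meta list with `animal_id`, `peep_nominal`, `peep_measured`.
#' @return A data frame with one row per (slice, ROI): animal, peep_nominal,
#'   peep_measured, slice, roi, NAs, gas_area, analyzed_volume, ASnum, ASdim.
#' @export
compute_metrics <- function(labelmap, partition, mask,
                            meta = list(animal_id = "A1", peep_nominal = NA,
                                        peep_measured = NA)) {
  stopifnot(inherits(labelmap, "airspace_labels"),
            inherits(partition, "roi_partition"),
            inherits(mask, "parenchyma_mask"))
  if (is.null(labelmap$labels))
    stopf("labelmap is not delineated; run delineate_airspaces() first")
  if (!identical(dim(labelmap$labels), dim(mask$included)))
    stopf("labelmap and mask are not aligned")
  ns <- dim(labelmap$labels)[3]
  rois <- c("ALL", partition$band_names)
  out <- vector("list", ns * length(rois))
  k <- 0L
  for (s in seq_len(ns)) {
    lab <- labelmap$labels[, , s]
    band <- partition$band[, , s]
    pk <- labelmap$peaks[labelmap$peaks$slice == s, , drop = FALSE]
    labs_present <- sort(unique(lab[lab > 0]))
    if (length(labs_present) && !all(labs_present %in% pk$label))
      stopf("corrupt labelmap: slice %d has labels without a peak", s)
    pk_band <- if (nrow(pk)) band[cbind(pk$row, pk$col)] else integer(0)
    gas <- lab > 0
    for (roi in rois) {
      k <- k + 1L
      if (roi == "ALL") {
        nas <- nrow(pk)
        gas_area <- sum(gas)
      } else {
        code <- match(roi, partition$band_names)
        nas <- sum(pk_band == code)
        gas_area <- sum(gas & band == code)
      }
      vol <- roi_volume(mask, partition, roi, s)
      out[[k]] <- data.frame(
        animal = meta$animal_id, peep_nominal = meta$peep_nominal,
        peep_measured = meta$peep_measured, slice = s, roi = roi,
        NAs = nas, gas_area = gas_area, analyzed_volume = vol,
        ASnum = if (vol > 0) nas / vol else NA_real_,
        ASdim = if (nas > 0) gas_area / nas else NA_real_
      )
    }
  }
  do.call(rbind, out)
}

#' Pool per-slice metric records into the study table
#'
#' Per-slice records are retained as individual observations (no averaging),
#' grouped by (PEEP, ROI); group mean and SD are computed for the summary in
#' the published layout. Duplicate (animal, PEEP, slice, ROI) keys are an
#' error. Groups with a single observation keep SD = 0 and are flagged.
#'
#' @param records data frame(s) from [compute_metrics()] (rows concatenated).
#' @return A list of class `study_table`: `observations` (all per-slice
#'   rows) and `summary` (per PEEP x ROI: mean, SD and n of ASdim and ASnum).
#' @export
pool_slices <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  key <- paste(records$animal, records$peep_nominal, records$slice, records$roi)
  if (anyDuplicated(key))
    stopf("duplicate (animal, PEEP, slice, ROI) records")
  grp <- interaction(records$peep_nominal, records$roi, drop = TRUE)
  sd0 <- function(v) { v <- v[!is.na(v)]; if (length(v) < 2) 0 else sd(v) }
  summ <- do.call(rbind, lapply(split(records, grp), function(g) {
    data.frame(
      peep_nominal = g$peep_nominal[1], peep_measured = g$peep_measured[1],
      roi = g$roi[1],
      ASdim_mean = mean(g$ASdim, na.rm = TRUE), ASdim_sd = sd0(g$ASdim),
      ASdim_n = sum(!is.na(g$ASdim)),
      ASnum_mean = mean(g$ASnum, na.rm = TRUE), ASnum_sd = sd0(g$ASnum),
      ASnum_n = sum(!is.na(g$ASnum)),
      n = nrow(g), single_obs = nrow(g) == 1
    )
  }))
  summ <- summ[order(summ$roi, -summ$peep_nominal), ]
  row.names(summ) <- NULL
  structure(list(observations = records, summary = summ),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("study_table: %d per-slice observations, %d PEEP x ROI groups\n",
              nrow(x$observations), nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}
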