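#' Read and write grayscale image stacks as multi-page TIFF
#'
#' Stacks are stored as multi-page 16-bit grayscale TIFF (one page per
#' slice); label maps as multi-page 32-bit float TIFF (labels are exact up to
#' 2^24); masks as 8-bit binary TIFF. The physical voxel size travels in a
#' JSON sidecar written by [write_series()] or must be supplied on read.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @param voxel_side voxel side (um) for the stack being read.
#' @return `write_stack_tiff()` returns `path` invisibly; `read_stack_tiff()`
#'   an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(stack$n_slices), function(s)
    stack$voxels[, , s] / GRAY_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, voxel_side = 47.7) {
  pages <- tiff::readTIFF(path, all = TRUE)
  vox <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (s in seq_along(pages)) vox[, , s] <- round(pages[[s]][, ] * GRAY_MAX)
  image_stack(vox, voxel_side)
}

#' @rdname write_stack_tiff
#' @param labels integer label array (e.g. `phantom_truth$label_map` or
#'   `airspace_labels$labels`); values in -3 .. 65532 survive the round trip
#'   exactly (stored as 32-bit float TIFF on the unit scale).
#' @export
write_labels_tiff <- function(labels, path) {
  if (min(labels) < -3 || max(labels) > GRAY_MAX - 3)
    stopf("label values outside the encodable range [-3, %d]", GRAY_MAX - 3)
  pages <- lapply(seq_len(dim(labels)[3]), function(s)
    (labels[, , s] + 3) / GRAY_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_labels_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lab <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (s in seq_along(pages))
    lab[, , s] <- as.integer(round(pages[[s]][, ] * GRAY_MAX) - 3)
  lab
}

#' @rdname write_stack_tiff
#' @param mask a [parenchyma_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "parenchyma_mask"))
  pages <- lapply(seq_len(dim(mask$included)[3]), function(s)
    mask$included[, , s] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_mask_tiff <- function(path, voxel_side = 47.7) {
  pages <- tiff::readTIFF(path, all = TRUE)
  inc <- array(FALSE, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (s in seq_along(pages)) inc[, , s] <- pages[[s]][, ] > 0.5
  parenchyma_mask(inc, voxel_side = voxel_side)
}

#' Write a rendered phantom PEEP series to disk
#'
#' One image TIFF, one truth-label TIFF and one mask TIFF per pressure
#' level, plus a JSON sidecar recording the spec, the seed, the fractions
#' and the pressures.
#'
#' @param series a [make_peep_series()] result.
#' @param dir output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "peep_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(voxel_side = series[[1]]$image$voxel_side,
               spec = unclass(series[[1]]$truth$spec),
               levels = list())
  for (i in seq_along(series)) {
    lv <- series[[i]]
    stem <- sprintf("level%02d_peep%02g", i, lv$peep)
    write_stack_tiff(lv$image, file.path(dir, paste0(stem, "_image.tif")))
    write_labels_tiff(lv$truth$label_map,
                      file.path(dir, paste0(stem, "_truth.tif")))
    write_mask_tiff(lv$mask, file.path(dir, paste0(stem, "_mask.tif")))
    meta$levels[[i]] <- list(peep = lv$peep, fraction = lv$fraction,
                             stem = stem)
  }
  sidecar <- file.path(dir, "series.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write study outputs to a directory
#'
#' Persists the per-slice study table and the summary layout (per PEEP x ROI
#' mean, SD and the regression parameters) as CSV, the regression and test
#' objects as JSON, and a run manifest (config snapshot, warning ledger,
#' output checksums) as JSON. Re-running an identical analysis reproduces
#' byte-identical CSVs.
#'
#' @param result a `study_result` from [run_study()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study_outputs <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_obs <- file.path(dir, "study_table.csv")
  f_sum <- file.path(dir, "summary_table.csv")
  f_reg <- file.path(dir, "regressions.json")
  write.csv(result$table$observations, f_obs, row.names = FALSE)
  summ <- merge(result$table$summary,
                stats::reshape(result$regression_table,
                               direction = "wide", idvar = "roi",
                               timevar = "response"),
                by = "roi", all.x = TRUE, sort = FALSE)
  write.csv(summ[order(summ$roi, -summ$peep_nominal), ], f_sum,
            row.names = FALSE)
  strip_data <- function(r) r[setdiff(names(r), c("x", "y"))]
  jsonlite::write_json(
    list(regressions = lapply(result$regressions, function(r)
           if (is.null(r)) NULL else strip_data(unclass(r))),
         ftests = result$ftests, wilcoxon = result$wilcoxon),
    f_reg, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- result$manifest
  manifest$outputs <- as.list(tools::md5sum(c(f_obs, f_sum, f_reg)))
  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA)
  invisible(f_man)
}
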