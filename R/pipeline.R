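#' Segment one stack end to end
#'
#' Convenience chain for a single (animal, PEEP) stack: exclusion of
#' non-ventilated regions, top-hat enhancement, peak counting, delineation.
#'
#' @param image raw [image_stack()].
#' @param mask [parenchyma_mask()].
#' @param tissue_threshold grayscale value separating gas from tissue
#'   density; also used as the density threshold for the flooded-region
#'   exclusion.
#' @param config a [study_config()].
#' @return A list with `mask` (after exclusion), `enhanced`, `labels`
#'   (a delineated `airspace_labels`).
#' @export
segment_stack <- function(image, mask, tissue_threshold,
                          config = study_config()) {
  mask2 <- exclude_nonventilated(image, mask, tissue_threshold,
                                 min_region = config$min_region,
                                 deep_radius = config$deep_radius,
                                 max_hole = config$max_hole)
  enhanced <- tophat_enhance(image, mask2, radii = config$radii,
                             smooth_sigma = config$smooth_sigma)
  counted <- count_airspaces(enhanced, mask2, h_depth = config$h_depth,
                             min_separation = config$min_separation,
                             image = image, tissue_threshold = tissue_threshold)
  labels <- delineate_airspaces(image, counted, mask2, tissue_threshold)
  list(mask = mask2, enhanced = enhanced, labels = labels)
}

#' Run the full study analysis over a set of stacks
#'
#' Orchestrates the full chain per (animal, PEEP) case — exclusion,
#' enhancement, counting, delineation, ROI banding, metrics — pools the
#' per-slice records, fits the PEEP regressions per response and ROI, runs
#' the F-test comparisons between the significant single-ROI regressions
#' (Bonferroni-corrected within each response family), and runs
#' Wilcoxon signed-rank comparisons of each metric between ROI pairs
#' (Bonferroni-corrected). A case whose mask is missing is skipped with a
#' logged warning; a geometry mismatch aborts.
#'
#' @param cases list of cases, each a list with `animal`, `peep_nominal`,
#'   `peep_measured`, `image` ([image_stack()]), `mask`
#'   ([parenchyma_mask()]), `tissue_threshold`.
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, the study table,
#'   the summary layout, the regression JSON and the run manifest are
#'   written there (see [write_study_outputs()]).
#' @return An object of class `study_result`: `table` (a `study_table`),
#'   `regressions` (list of `peep_regression`), `regression_table` (data
#'   frame), `ftests`, `wilcoxon`, `config`, `manifest`.
#' @export
run_study <- function(cases, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  t0 <- proc.time()[["elapsed"]]
  warnings_log <- character(0)
  records <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (is.null(cs$mask)) {
      warnings_log <- c(warnings_log,
                        sprintf("case %d skipped: missing mask", i))
      next
    }
    if (!identical(dim(cs$image$voxels), dim(cs$mask$included)))
      stopf("case %d: image/mask geometry mismatch", i)
    seg <- segment_stack(cs$image, cs$mask, cs$tissue_threshold, config)
    dist <- pleural_distance_map(seg$mask)
    part <- partition_rois(dist, config$offsets, seg$mask)
    records[[length(records) + 1]] <- compute_metrics(
      seg$labels, part, seg$mask,
      meta = list(animal_id = cs$animal, peep_nominal = cs$peep_nominal,
                  peep_measured = cs$peep_measured))
    if (seg$labels$dropped_peaks > 0)
      warnings_log <- c(warnings_log,
                        sprintf("case %d: %d peak(s) dropped at tissue density",
                                i, seg$labels$dropped_peaks))
  }
  if (length(records) == 0) stopf("no analyzable cases")
  table <- pool_slices(do.call(rbind, records))

  rois <- c("ALL", "SUB", "MAN", "COR")
  regs <- list()
  for (resp in c("ASdim", "ASnum"))
    for (roi in rois)
      regs[paste(resp, roi, sep = "_")] <- list(tryCatch(
        fit_peep_regression(table, resp, roi, config$regressor),
        error = function(e) {
          warnings_log <<- c(warnings_log,
                             sprintf("regression %s/%s failed: %s",
                                     resp, roi, conditionMessage(e)))
          NULL
        }))
  reg_table <- do.call(rbind, lapply(names(regs), function(nm) {
    r <- regs[[nm]]
    if (is.null(r)) {
      parts <- strsplit(nm, "_")[[1]]
      return(data.frame(response = parts[1], roi = parts[2], m = NA_real_,
                        k = NA_real_, r_squared = NA_real_,
                        p_value = NA_real_, n = 0L, significant = NA))
    }
    data.frame(response = r$response, roi = r$roi, m = r$m, k = r$k,
               r_squared = r$r_squared, p_value = r$p_value, n = r$n,
               significant = r$p_value <= config$alpha)
  }))
  row.names(reg_table) <- NULL

  # F-tests: within each response, compare the significant single-ROI
  # regressions pairwise; Bonferroni over the family
  ftests <- list()
  for (resp in c("ASdim", "ASnum")) {
    sig <- Filter(function(r) !is.null(r) && r$roi != "ALL" &&
                    r$p_value <= config$alpha,
                  regs[grep(paste0("^", resp), names(regs))])
    if (length(sig) >= 2) {
      prs <- utils::combn(names(sig), 2, simplify = FALSE)
      fam <- lapply(prs, function(pr)
        c(compare_regressions_ftest(sig[[pr[1]]], sig[[pr[2]]],
                                    alpha = config$alpha),
          list(pair = pr)))
      corr <- bonferroni(vapply(fam, `[[`, numeric(1), "p_value"),
                         config$alpha)
      for (j in seq_along(fam)) {
        fam[[j]]$significant_bonferroni <- corr$significant[j]
        fam[[j]]$family_size <- corr$m
      }
      ftests[[resp]] <- fam
    }
  }

  # Wilcoxon: each metric compared between ROI pairs, paired per
  # (animal, PEEP, slice) observation; Bonferroni over the three pairs
  wilcox <- list()
  obs <- table$observations
  for (resp in c("ASdim", "ASnum")) {
    prs <- utils::combn(c("SUB", "MAN", "COR"), 2, simplify = FALSE)
    fam <- lapply(prs, function(pr) {
      a <- obs[obs$roi == pr[1], ]
      b <- obs[obs$roi == pr[2], ]
      keya <- paste(a$animal, a$peep_nominal, a$slice)
      keyb <- paste(b$animal, b$peep_nominal, b$slice)
      b <- b[match(keya, keyb), ]
      ok <- !is.na(a[[resp]]) & !is.na(b[[resp]])
      if (sum(ok) < 1) return(NULL)
      c(wilcoxon_signed_rank(a[[resp]][ok], b[[resp]][ok]),
        list(pair = pr))
    })
    fam <- Filter(Negate(is.null), fam)
    if (length(fam)) {
      corr <- bonferroni(vapply(fam, `[[`, numeric(1), "p_value"),
                         config$alpha)
      for (j in seq_along(fam)) {
        fam[[j]]$significant_bonferroni <- corr$significant[j]
        fam[[j]]$family_size <- corr$m
      }
      wilcox[[resp]] <- fam
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("airspacer")),
    config = unclass(config),
    n_cases = length(cases),
    n_observations = nrow(table$observations),
    warnings = warnings_log,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)
  )
  res <- structure(list(table = table, regressions = regs,
                        regression_table = reg_table, ftests = ftests,
                        wilcoxon = wilcox, config = config,
                        manifest = manifest),
                   class = "study_result")
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result\n")
  print(x$regression_table, digits = 3)
  if (length(x$manifest$warnings))
    cat("warnings:", length(x$manifest$warnings), "\n")
  invisible(x)
}

#' Simulate a full decremental-PEEP experiment on a phantom
#'
#' The synthetic twin of the imaging protocol: a phantom series is generated
#' under the chosen deflation mechanism ([make_peep_series()]), analyzed end
#' to end with [run_study()], and the measured metrics are compared with the
#' generator's ground truth per pressure level.
#'
#' @param spec a [phantom_spec()].
#' @param mechanism deflation mechanism (see [apply_deflation()]).
#' @param fractions non-decreasing deflation fractions, one per PEEP level.
#' @param config a [study_config()]; its PEEP ladder defines the levels.
#' @param level_scatter per-slice fraction scatter (see [make_peep_series()]).
#' @param out_dir optional output directory.
#' @return A `study_result` with an extra `truth_comparison` data frame
#'   (per level: true open count and mean area vs measured NAs and ASdim)
#'   and the generating `spec`.
#' @export
simulate_experiment <- function(spec, mechanism, fractions,
                                config = study_config(),
                                level_scatter = 0, out_dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(config, "study_config"))
  if (length(fractions) != length(config$peep_nominal))
    stopf("need one fraction per PEEP level")
  series <- make_peep_series(spec, mechanism, config$peep_nominal, fractions,
                             level_scatter = level_scatter)
  thr <- (spec$gas_level + spec$tissue_level) / 2
  cases <- lapply(seq_along(series), function(i)
    list(animal = "phantom", peep_nominal = config$peep_nominal[i],
         peep_measured = config$peep_measured[i],
         image = series[[i]]$image, mask = series[[i]]$mask,
         tissue_threshold = thr))
  res <- run_study(cases, config, out_dir = NULL)
  obs <- res$table$observations
  res$truth_comparison <- do.call(rbind, lapply(seq_along(series), function(i) {
    lv <- series[[i]]
    all_obs <- obs[obs$roi == "ALL" & obs$peep_nominal == lv$peep, ]
    true_n <- truth_open_counts(lv$truth)
    data.frame(
      peep = lv$peep, fraction = lv$fraction,
      true_open_mean = mean(true_n),
      nas_mean = mean(all_obs$NAs),
      nas_abs_err = mean(abs(all_obs$NAs[order(all_obs$slice)] - true_n)),
      true_mean_area = mean(truth_mean_area(lv$truth)),
      asdim_mean = mean(all_obs$ASdim, na.rm = TRUE)
    )
  }))
  res$spec <- spec
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}
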