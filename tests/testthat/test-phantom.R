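test_that("generator produces the requested airspace count, deterministically", {
  sp <- resolvable_spec(n_slices = 2, seed = 7)
  tr <- generate_parenchyma_truth(sp)
  for (s in 1:2) {
    lab <- tr$label_map[, , s]
    expect_equal(length(unique(lab[lab > 0])), 25)
  }
  expect_identical(tr$label_map, generate_parenchyma_truth(sp)$label_map)
  sp2 <- resolvable_spec(n_slices = 2, seed = 8)
  expect_false(identical(tr$label_map,
                         generate_parenchyma_truth(sp2)$label_map))
})

test_that("label conservation: per-airspace areas sum to the gas voxel count", {
  tr <- generate_parenchyma_truth(resolvable_spec(n_slices = 2))
  expect_identical(sum(tr$airspaces$area), sum(tr$label_map > 0))
  d <- apply_deflation(tr, "balloon", 0.35)
  expect_identical(sum(d$airspaces$area), sum(d$label_map > 0))
  d <- apply_deflation(tr, "derecruitment", 0.35)
  expect_identical(sum(d$airspaces$area), sum(d$label_map > 0))
})

test_that("realized mean equivalent diameter is within 15% of the spec value", {
  sp <- phantom_spec(domain_radius = 2, target_count = 150,
                     mean_airspace_diameter = 110, septal_thickness = 100,
                     n_slices = 3, seed = 5)
  tr <- generate_parenchyma_truth(sp)
  eq_diam <- 2 * sqrt(tr$airspaces$area / pi) * sp$voxel_side
  expect_gte(mean(eq_diam), 93.5)
  expect_lte(mean(eq_diam), 126.5)
})

test_that("septa separate airspaces by at least the requested thickness", {
  sp <- resolvable_spec(n_slices = 1)
  tr <- generate_parenchyma_truth(sp)
  lab <- tr$label_map[, , 1]
  # no two different labels may be 8-adjacent (septa >= 2 voxels)
  idx <- which(lab > 0, arr.ind = TRUE)
  for (dr in -1:1) for (dc in -1:1) {
    nb <- cbind(idx[, 1] + dr, idx[, 2] + dc)
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(lab) & nb[, 2] >= 1 & nb[, 2] <= ncol(lab)
    v <- lab[nb[ok, , drop = FALSE]]
    w <- lab[idx[ok, , drop = FALSE]]
    expect_true(all(v <= 0 | v == w))
  }
})

test_that("infeasible packing raises a capacity error", {
  sp <- phantom_spec(domain_radius = 0.5, target_count = 500,
                     mean_airspace_diameter = 120, n_slices = 1)
  expect_error(generate_parenchyma_truth(sp), "infeasible packing")
})

test_that("balloon deflation scales areas, preserves identity and count", {
  sp <- phantom_spec(domain_radius = 1.8, target_count = 50,
                     mean_airspace_diameter = 200, septal_thickness = 96,
                     n_slices = 1, seed = 3)
  tr <- generate_parenchyma_truth(sp)
  d <- apply_deflation(tr, "balloon", 0.4)
  expect_equal(sum(d$airspaces$open), 50)
  # per-region quantization tolerance is +-1 voxel
  expect_true(all(abs(d$airspaces$area - (1 - 0.4) * tr$airspaces$area) <= 1))
  # nesting: a lighter deflation contains the heavier one
  d2 <- apply_deflation(tr, "balloon", 0.2)
  expect_true(all(mapply(function(a, b) all(b %in% a),
                         d2$pixels[[1]], d$pixels[[1]])))
})

test_that("derecruitment closes round(fraction * N) airspaces, survivors intact", {
  sp <- phantom_spec(domain_radius = 1.8, target_count = 50,
                     mean_airspace_diameter = 200, septal_thickness = 96,
                     n_slices = 1, seed = 3)
  tr <- generate_parenchyma_truth(sp)
  d <- apply_deflation(tr, "derecruitment", 0.4)
  expect_equal(sum(d$airspaces$open), 30)
  surv <- d$airspaces$open
  expect_identical(d$airspaces$area[surv], tr$airspaces$area[surv])
  expect_true(all(d$airspaces$area[!surv] == 0))
  # closures nest across non-decreasing fractions applied to the same base
  d2 <- apply_deflation(tr, "derecruitment", 0.2)
  expect_true(all(d$airspaces$open <= d2$airspaces$open))
})

test_that("mixed mode shrinks survivors and closes airspaces", {
  tr <- generate_parenchyma_truth(resolvable_spec(n_slices = 1, seed = 9))
  d <- apply_deflation(tr, "mixed", 0.4)
  expect_lt(sum(d$airspaces$open), nrow(d$airspaces))
  surv <- d$airspaces$open
  expect_true(all(d$airspaces$area[surv] < tr$airspaces$area[surv]))
})

test_that("deflation identity, argument validation and reserved mechanisms", {
  tr <- generate_parenchyma_truth(resolvable_spec(n_slices = 1))
  expect_identical(apply_deflation(tr, "balloon", 0), tr)
  expect_identical(apply_deflation(tr, "none", 0.5), tr)
  expect_error(apply_deflation(tr, "balloon", 1.2), "\\[0, 1\\]")
  expect_error(apply_deflation(tr, "implosion", 0.2))
  expect_error(apply_deflation(tr, "crumpling", 0.2), "reserved")
})

test_that("noiseless rendering is two-valued; fringes overshoot by the set amplitude", {
  sp <- resolvable_spec(n_slices = 1)
  tr <- generate_parenchyma_truth(sp)
  img <- render_image(tr)
  vals <- unique(as.vector(img$voxels[tr$parenchyma]))
  expect_setequal(vals, c(sp$gas_level, sp$tissue_level))
  spf <- resolvable_spec(n_slices = 1, fringe_amplitude = 1500)
  imgf <- render_image(generate_parenchyma_truth(spf), spf)
  expect_equal(min(imgf$voxels[tr$parenchyma]), spf$gas_level - 1500)
  expect_equal(max(imgf$voxels[tr$parenchyma]), spf$tissue_level + 1500)
})

test_that("rendering is a pure function of (truth, spec, seed)", {
  sp <- resolvable_spec(n_slices = 2, noise_sigma = 2000, fringe_amplitude = 1000)
  tr <- generate_parenchyma_truth(sp)
  expect_identical(render_image(tr, sp)$voxels, render_image(tr, sp)$voxels)
  expect_false(identical(render_image(tr, sp, seed = 1)$voxels,
                         render_image(tr, sp, seed = 2)$voxels))
})

test_that("rendering clips out-of-range values with a warning and a count", {
  sp <- resolvable_spec(n_slices = 1, fringe_amplitude = 30000)
  tr <- generate_parenchyma_truth(sp)
  expect_warning(img <- render_image(tr, sp), "clipped")
  expect_gt(img$n_clipped, 0)
  expect_lte(max(img$voxels), 65535)
})

test_that("make_peep_series: balloon keeps counts, derecruitment steps them down", {
  sp <- resolvable_spec(n_slices = 2, seed = 21)
  fr <- c(0, .1, .2, .3, .4)
  sb <- make_peep_series(sp, "balloon", c(12, 9, 6, 3, 0), fr)
  expect_length(sb, 5)
  counts <- sapply(sb, function(lv) mean(truth_open_counts(lv$truth)))
  expect_true(all(counts == 25))
  sd_ <- make_peep_series(sp, "derecruitment", c(12, 9, 6, 3, 0), fr)
  counts <- sapply(sd_, function(lv) truth_open_counts(lv$truth)[1])
  expect_equal(counts, 25 - round(fr * 25))
})

test_that("make_peep_series validates inputs and the single-level identity", {
  sp <- resolvable_spec(n_slices = 1)
  expect_error(make_peep_series(sp, "balloon", c(12, 9), 0.1), "same length")
  expect_error(make_peep_series(sp, "balloon", c(12, 9), c(0.3, 0.1)),
               "non-decreasing")
  s1 <- make_peep_series(sp, "balloon", 12, 0)
  base <- render_image(generate_parenchyma_truth(sp), sp,
                       seed = sp$seed + 501L)
  expect_identical(s1[[1]]$image$voxels, base$voxels)
})

test_that("flooded cap occupies the requested peripheral fraction", {
  sp <- phantom_spec(domain_radius = 2.5, target_count = 60,
                     mean_airspace_diameter = 195, septal_thickness = 100,
                     flooded_fraction = 0.15, n_slices = 1, seed = 13)
  tr <- generate_parenchyma_truth(sp)
  frac <- sum(tr$flooded[, , 1]) / sum(tr$parenchyma[, , 1])
  expect_equal(frac, 0.15, tolerance = 0.02)
  # the cap touches the pleural boundary
  expect_true(any(tr$flooded[, , 1] &
                    !EBImage::erode(tr$parenchyma[, , 1],
                                    EBImage::makeBrush(3, "box"))))
  # no airspace voxels inside the cap
  expect_true(all(tr$label_map[, , 1][tr$flooded[, , 1]] == -2L))
})
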