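test_that("top-hat enhancement equals the brute-force closing residue exactly", {
  set.seed(31)
  x <- matrix(round(runif(24 * 20, 1000, 50000)), 24, 20)
  img <- stack_of(x)
  msk <- full_mask_of(x)
  for (radii in list(1, c(1, 2), c(2, 3))) {
    enh <- tophat_enhance(img, msk, radii = radii, smooth_sigma = 0)
    oracle <- Reduce(pmax, lapply(radii, function(r)
      pmax(brute_black_tophat(x, r), 0)))
    expect_equal(enh$voxels[, , 1], oracle, tolerance = 1e-8)
  }
})

test_that("top-hat turns an isolated dark pixel into its depth, flat images into 0", {
  x <- matrix(100, 9, 9); x[5, 5] <- 60
  enh <- tophat_enhance(stack_of(x), full_mask_of(x), radii = 1,
                        smooth_sigma = 0)
  expect_equal(enh$voxels[5, 5, 1], 40)
  expect_true(all(enh$voxels[-5, , 1] == 0) && all(enh$voxels[5, -5, 1] == 0))
  flat <- matrix(500, 12, 12)
  expect_true(all(tophat_enhance(stack_of(flat), full_mask_of(flat),
                                 radii = c(1, 2), smooth_sigma = 0)$voxels == 0))
})

test_that("larger structuring elements respond at least as strongly on a wide disc", {
  x <- matrix(100, 21, 21)
  ctr <- 11
  rr <- matrix(seq_len(21), 21, 21)
  x[(rr - ctr)^2 + (t(rr) - ctr)^2 <= 3^2] <- 40  # dark disc, diameter ~6
  r2 <- pmax(brute_black_tophat(x, 2), 0)
  r4 <- pmax(brute_black_tophat(x, 4), 0)
  expect_gte(r4[ctr, ctr], r2[ctr, ctr])
  enh <- tophat_enhance(stack_of(x), full_mask_of(x), radii = c(2, 4),
                        smooth_sigma = 0)
  expect_equal(enh$voxels[ctr, ctr, 1], r4[ctr, ctr])
})

test_that("tophat_enhance validates its inputs", {
  x <- matrix(1, 5, 5)
  expect_error(tophat_enhance(stack_of(x), full_mask_of(x), radii = numeric(0)),
               "non-empty")
  expect_error(tophat_enhance(stack_of(x), full_mask_of(x), radii = 0.4),
               ">= 1")
  expect_error(tophat_enhance(stack_of(x), full_mask_of(x), radii = c(3, 2)),
               "ascending")
})

test_that("h-maxima counting separates peaks by prominence", {
  # two isolated peaks of prominence 40 and 5: only one survives h_depth = 10
  e <- matrix(0, 15, 15)
  e[4, 4] <- 40
  e[11, 11] <- 5
  cnt <- count_airspaces(stack_of(e), full_mask_of(e), h_depth = 10,
                         min_separation = 0)
  expect_equal(cnt$nas_per_slice, 1L)
  expect_equal(cnt$peaks[, c("row", "col")],
               data.frame(row = 4, col = 4))
})

test_that("a flat enhanced image has no peaks; h_depth must be positive", {
  e <- matrix(0, 10, 10)
  cnt <- count_airspaces(stack_of(e), full_mask_of(e), h_depth = 5)
  expect_equal(cnt$nas_per_slice, 0L)
  expect_equal(nrow(cnt$peaks), 0L)
  expect_error(count_airspaces(stack_of(e), full_mask_of(e), h_depth = 0),
               "h_depth")
})

test_that("a connected plateau counts as one peak at its centroid", {
  e <- matrix(0, 11, 11)
  e[5:7, 5:7] <- 30   # 3x3 plateau centred at (6, 6)
  cnt <- count_airspaces(stack_of(e), full_mask_of(e), h_depth = 10,
                         min_separation = 0)
  expect_equal(cnt$nas_per_slice, 1L)
  expect_equal(cnt$peaks$row, 6)
  expect_equal(cnt$peaks$col, 6)
})

test_that("peaks closer than min_separation merge, keeping the highest", {
  e <- matrix(0, 12, 12)
  e[5, 5] <- 30
  e[5, 7] <- 50  # 2 voxels away
  cnt <- count_airspaces(stack_of(e), full_mask_of(e), h_depth = 10,
                         min_separation = 3 * 47.7)
  expect_equal(cnt$nas_per_slice, 1L)
  expect_equal(cnt$peaks$col, 7)
  # beyond the separation both survive
  cnt2 <- count_airspaces(stack_of(e), full_mask_of(e), h_depth = 10,
                          min_separation = 1.5 * 47.7)
  expect_equal(cnt2$nas_per_slice, 2L)
})

test_that("noiseless phantom counts are exact on every slice", {
  sp <- resolvable_spec(n_slices = 3, seed = 7)
  tr <- generate_parenchyma_truth(sp)
  seg <- segment_stack(render_image(tr), phantom_mask(tr), mid_threshold(sp))
  expect_equal(seg$labels$nas_per_slice, truth_open_counts(tr))
})

test_that("counts stay within 5% under 10% contrast noise", {
  errs <- sapply(1:3, function(k) {
    sp <- study_scale_spec(n_slices = 1, seed = 300 + k)
    tr <- generate_parenchyma_truth(sp)
    seg <- segment_stack(render_image(tr), phantom_mask(tr), mid_threshold(sp))
    mean(abs(seg$labels$nas_per_slice - truth_open_counts(tr)) /
           truth_open_counts(tr))
  })
  expect_lte(mean(errs), 0.05)
})

test_that("delineation respects septa and fills uniform discs", {
  x <- matrix(45000, 20, 20)
  x[5:9, 4:8] <- 20000          # disc A
  x[5:9, 11:15] <- 20000        # disc B, separated by a 2-voxel septum
  img <- stack_of(x); msk <- full_mask_of(x)
  pk <- data.frame(slice = 1L, row = c(7, 7), col = c(6, 13), value = 1)
  del <- delineate_airspaces(img, pk, msk, tissue_threshold = 32500)
  expect_equal(del$nas_per_slice, 2L)
  lab <- del$labels[, , 1]
  expect_true(all(lab[, 9:10] == 0))            # septum untouched
  expect_equal(sum(lab == 1), 25)
  expect_equal(sum(lab == 2), 25)
  # single peak in a uniform dark disc claims the whole disc
  y <- matrix(45000, 15, 15); y[4:10, 4:10] <- 20000
  del1 <- delineate_airspaces(stack_of(y),
                              data.frame(slice = 1L, row = 7, col = 7, value = 1),
                              full_mask_of(y), 32500)
  expect_equal(del1$peaks$area, 49L)
})

test_that("peaks at tissue density are dropped and reported", {
  x <- matrix(45000, 10, 10); x[3:5, 3:5] <- 20000
  pk <- data.frame(slice = 1L, row = c(4, 8), col = c(4, 8), value = 1)
  del <- delineate_airspaces(stack_of(x), pk, full_mask_of(x), 32500)
  expect_equal(del$dropped_peaks, 1L)
  expect_equal(del$nas_per_slice, 1L)
})

test_that("noiseless phantom per-airspace areas are within 10% of truth", {
  sp <- resolvable_spec(n_slices = 2, seed = 17)
  tr <- generate_parenchyma_truth(sp)
  seg <- segment_stack(render_image(tr), phantom_mask(tr), mid_threshold(sp))
  for (s in 1:2) {
    lab <- seg$labels$labels[, , s]
    pk <- seg$labels$peaks[seg$labels$peaks$slice == s, ]
    truth_lab <- tr$label_map[, , s]
    true_id <- truth_lab[cbind(pk$row, pk$col)]
    expect_true(all(true_id > 0))
    true_area <- tr$airspaces$area[match(true_id, tr$airspaces$id)]
    expect_true(all(abs(pk$area - true_area) / true_area <= 0.10))
  }
})

test_that("a perimeter flooded cap is excluded exactly, interior blobs retained", {
  n <- 90
  x <- matrix(20000, n, n)
  x[1:45, 21:65] <- 45000        # 2025-voxel dense cap touching row 1
  x[70:75, 25:30] <- 45000       # 36-voxel interior blob (< min_region)
  msk <- full_mask_of(x)
  m2 <- exclude_nonventilated(stack_of(x), msk, 32500, min_region = 50)
  expect_equal(sum(m2$excluded_nonventilated), 2025)
  expect_true(all(which(m2$excluded_nonventilated[, , 1]) ==
                    which(x == 45000 & row(x) <= 45)))
  # interior dense region large and deep but not touching the perimeter stays
  y <- matrix(20000, n, n)
  y[21:69, 21:69] <- 45000
  m3 <- exclude_nonventilated(stack_of(y), full_mask_of(y), 32500)
  expect_equal(sum(m3$excluded_nonventilated), 0)
})

test_that("exclusion is inert without dense voxels and validates the threshold", {
  x <- matrix(20000, 30, 30)
  msk <- full_mask_of(x)
  m2 <- exclude_nonventilated(stack_of(x), msk, 20000, min_region = 10)
  # threshold at the gas level: everything dense, but depth never exceeded
  expect_error(exclude_nonventilated(stack_of(x), msk, 99999), "outside image range")
  x[1, 1] <- 45000
  m3 <- exclude_nonventilated(stack_of(x), msk, 32500)
  expect_identical(m3$included, msk$included)
})

test_that("enlarging the flooded cap never increases the analyzed volume", {
  vols <- sapply(c(0.05, 0.15, 0.3), function(ff) {
    sp <- phantom_spec(domain_radius = 5, target_count = 300,
                       mean_airspace_diameter = 195, septal_thickness = 100,
                       flooded_fraction = ff, n_slices = 1, seed = 11)
    tr <- generate_parenchyma_truth(sp)
    m2 <- exclude_nonventilated(render_image(tr), phantom_mask(tr),
                                mid_threshold(sp))
    sum(m2$included)
  })
  expect_true(all(diff(vols) < 0))
})
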