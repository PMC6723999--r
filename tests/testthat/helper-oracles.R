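# independent brute-force oracles and shared fixtures

# grayscale dilation/erosion/closing by exhaustive neighborhood max/min with
# a disc structuring element; pixels outside the image are ignored
brute_dilate <- function(x, radius) {
  br <- EBImage::makeBrush(2 * radius + 1, "disc")
  off <- which(br > 0, arr.ind = TRUE) - (radius + 1)
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    ri <- i + off[, 1]; cj <- j + off[, 2]
    k <- ri >= 1 & ri <= nrow(x) & cj >= 1 & cj <= ncol(x)
    out[i, j] <- max(x[cbind(ri[k], cj[k])])
  }
  out
}

brute_erode <- function(x, radius) {
  br <- EBImage::makeBrush(2 * radius + 1, "disc")
  off <- which(br > 0, arr.ind = TRUE) - (radius + 1)
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    ri <- i + off[, 1]; cj <- j + off[, 2]
    k <- ri >= 1 & ri <= nrow(x) & cj >= 1 & cj <= ncol(x)
    out[i, j] <- min(x[cbind(ri[k], cj[k])])
  }
  out
}

brute_black_tophat <- function(x, radius) {
  brute_erode(brute_dilate(x, radius), radius) - x
}

# closed-form simple OLS
brute_ols <- function(x, y) {
  m <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(m = m, k = mean(y) - m * mean(x))
}

# exact Wilcoxon signed-rank p by explicit enumeration over sign vectors
brute_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
}

# minimal observations table for the regression layer
obs_frame <- function(x, y, roi = "ALL") {
  data.frame(animal = "a", peep_nominal = x, peep_measured = x,
             slice = seq_along(x), roi = roi, NAs = 1, gas_area = 1,
             analyzed_volume = 1, ASnum = y, ASdim = y)
}

# a full-mask image stack from a matrix
stack_of <- function(m, voxel_side = 47.7) image_stack(m, voxel_side)
full_mask_of <- function(m, voxel_side = 47.7)
  parenchyma_mask(array(TRUE, dim = c(dim(m), 1L)), voxel_side = voxel_side)

# disc-shaped mask of given radius (mm)
disc_mask <- function(radius_mm, voxel_side = 47.7, n_slices = 1) {
  r_vox <- radius_mm * 1000 / voxel_side
  n <- 2L * ceiling(r_vox) + 5L
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  disc <- (rr - ctr)^2 + (t(rr) - ctr)^2 <= r_vox^2
  parenchyma_mask(array(disc, dim = c(n, n, n_slices)), voxel_side = voxel_side)
}

# the resolvable-scale phantom used across segmentation tests: airspaces of
# ~4.5 voxel diameter with >= 2 voxel septa
resolvable_spec <- function(n_slices = 3, seed = 7, ...) {
  phantom_spec(domain_radius = 1.6, target_count = 25,
               mean_airspace_diameter = 215, septal_thickness = 96,
               n_slices = n_slices, seed = seed, ...)
}

# study-scale phantom: metric magnitudes comparable to the published tables
# (ASdim ~ 13 voxels at full inflation), acquisition-like noise (10% of the
# gas--tissue contrast) and phase-contrast fringes
study_scale_spec <- function(n_slices = 40, seed = 42, ...) {
  phantom_spec(domain_radius = 5, target_count = 400,
               mean_airspace_diameter = 195, septal_thickness = 100,
               noise_sigma = 2500, fringe_amplitude = 3000,
               n_slices = n_slices, seed = seed, ...)
}

mid_threshold <- function(spec) (spec$gas_level + spec$tissue_level) / 2

# cache for results shared between acceptance blocks
.acceptance_cache <- new.env(parent = emptyenv())

# between-slice scatter of the applied deflation fraction: wide for the
# ARDS-like balloon series (the injured-lung tables show SDs growing to
# ~half the mean at low pressure), narrower for the healthy-like
# derecruitment series (healthy-condition scatter is reported much smaller)
headline_scatter <- function(mechanism) {
  if (mechanism == "balloon") 0.8 else 0.25
}

headline_result <- function(mechanism) {
  key <- paste0("headline_", mechanism)
  if (is.null(.acceptance_cache[[key]])) {
    sp <- study_scale_spec(n_slices = 40, seed = 42)
    cfg <- study_config(n_slices = 40)
    .acceptance_cache[[key]] <- simulate_experiment(
      sp, mechanism, fractions = c(0, 0.1, 0.2, 0.3, 0.4),
      config = cfg, level_scatter = headline_scatter(mechanism))
  }
  .acceptance_cache[[key]]
}
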