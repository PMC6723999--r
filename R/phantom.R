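#' Phantom specification
#'
#' Parameters of the synthetic lung-slice phantom: a disc of parenchyma
#' tessellated into gas-filled airspaces separated by tissue-density septa,
#' optionally carrying a peripheral flooded/atelectatic cap, rendered with
#' phase-contrast-like boundary fringes and additive Gaussian noise.
#'
#' Geometry defaults follow the acquisition the package targets: isotropic
#' 47.7 um voxels and a mean airspace diameter of 110 um (the anatomical
#' alveolar scale, a little over twice the voxel side so single alveoli are
#' just resolvable). Airspaces must satisfy
#' `mean_airspace_diameter >= 2 * voxel_side`.
#'
#' @param domain_radius radius of the parenchyma disc (mm).
#' @param target_count number of airspaces per slice.
#' @param mean_airspace_diameter mean airspace equivalent diameter (um).
#' @param septal_thickness minimum tissue septum between airspaces (um).
#' @param gas_level,tissue_level grayscale values (16-bit units) for gas and
#'   tissue; `tissue_level > gas_level`.
#' @param noise_sigma sd of additive Gaussian noise (grayscale units).
#' @param fringe_amplitude amplitude of the one-voxel dark/bright
#'   phase-contrast overshoot pair at gas--tissue boundaries (grayscale units).
#' @param flooded_fraction fraction of the parenchyma occupied by a single
#'   peripheral flooded/atelectatic cap, in `[0, 1)`.
#' @param n_slices number of cranio-caudal slices.
#' @param voxel_side voxel side (um).
#' @param seed integer seed; every random choice of the generator flows from it.
#' @param diameter_cv coefficient of variation of per-airspace diameters
#'   (lognormal, mean-preserving).
#' @param slice_size_cv sd (log scale) of the per-slice global size factor;
#'   emulates cranio-caudal heterogeneity so pooled per-slice metrics scatter.
#' @param lattice_jitter seed-placement jitter as a fraction of the lattice
#'   spacing; 0 gives a regular hexagonal tessellation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(domain_radius = 5, target_count = 400,
                         mean_airspace_diameter = 110, septal_thickness = 100,
                         gas_level = 20000, tissue_level = 45000,
                         noise_sigma = 0, fringe_amplitude = 0,
                         flooded_fraction = 0, n_slices = 40,
                         voxel_side = 47.7, seed = 1L,
                         diameter_cv = 0.2, slice_size_cv = 0.08,
                         lattice_jitter = 0.2) {
  if (tissue_level <= gas_level) stopf("tissue_level must exceed gas_level")
  if (target_count < 1) stopf("target_count must be >= 1")
  if (mean_airspace_diameter < 2 * voxel_side)
    stopf("mean_airspace_diameter must be >= 2 voxel sides (resolvability)")
  if (noise_sigma < 0 || fringe_amplitude < 0)
    stopf("noise_sigma and fringe_amplitude must be >= 0")
  if (flooded_fraction < 0 || flooded_fraction >= 1)
    stopf("flooded_fraction must be in [0, 1)")
  if (n_slices < 1) stopf("n_slices must be >= 1")
  if (domain_radius <= 0 || voxel_side <= 0 || septal_thickness < 0)
    stopf("lengths must be positive")
  structure(
    list(domain_radius = domain_radius, target_count = as.integer(target_count),
         mean_airspace_diameter = mean_airspace_diameter,
         septal_thickness = septal_thickness,
         gas_level = gas_level, tissue_level = tissue_level,
         noise_sigma = noise_sigma, fringe_amplitude = fringe_amplitude,
         flooded_fraction = flooded_fraction, n_slices = as.integer(n_slices),
         voxel_side = voxel_side, seed = as.integer(seed),
         diameter_cv = diameter_cv, slice_size_cv = slice_size_cv,
         lattice_jitter = lattice_jitter),
    class = "phantom_spec"
  )
}

# jittered hexagonal seed placement over the eligible pixel set;
# returns an N x 2 matrix of continuous (row, col) coordinates
place_seeds <- function(eligible, n_seeds, jitter_frac, spec) {
  n <- nrow(eligible)
  a <- sqrt(2 * sum(eligible) / (sqrt(3) * n_seeds))
  phase <- runif(2, 0, a)
  eval_a <- function(a) {
    rows <- seq(1 + phase[1], n, by = sqrt(3) / 2 * a)
    pts <- do.call(rbind, lapply(seq_along(rows), function(k) {
      cols <- seq(1 + phase[2] + (k %% 2) * a / 2, n, by = a)
      if (!length(cols)) return(NULL)
      cbind(rows[k], cols)
    }))
    if (is.null(pts)) return(matrix(0, 0, 2))
    if (jitter_frac > 0)
      pts <- pts + matrix(runif(2 * nrow(pts), -jitter_frac * a, jitter_frac * a),
                          ncol = 2)
    ij <- round(pts)
    keep <- ij[, 1] >= 1 & ij[, 1] <= n & ij[, 2] >= 1 & ij[, 2] <= n
    keep[keep] <- eligible[ij[keep, , drop = FALSE]]
    pts[keep, , drop = FALSE]
  }
  # adjust the spacing so the lattice yields barely more sites than needed:
  # a large site surplus would leave deep vacancies in the tessellation
  pts <- eval_a(a)
  for (it in 1:8) {
    np <- nrow(pts)
    if (np >= n_seeds && np <= ceiling(1.06 * n_seeds)) break
    if (np == 0) { a <- a * 0.7 } else { a <- a * sqrt(np / (1.02 * n_seeds)) }
    pts <- eval_a(a)
  }
  if (nrow(pts) < n_seeds)
    stopf(paste0("infeasible packing: only %d candidate sites for %d airspaces ",
                 "(count x airspace area exceeds the domain capacity of the ",
                 "%.3g mm disc)"),
          nrow(pts), n_seeds, spec$domain_radius)
  # drop surplus sites where the lattice is most crowded, so no deep
  # tissue vacancy opens where a site is removed
  while (nrow(pts) > n_seeds) {
    dd <- as.matrix(stats::dist(pts))
    diag(dd) <- Inf
    pts <- pts[-which.min(apply(dd, 1, min)), , drop = FALSE]
  }
  pts
}

#' Generate ground-truth phantom parenchyma
#'
#' Builds a disc-shaped parenchyma tessellated into `target_count` gas
#' regions per slice, separated by septa of at least `septal_thickness`.
#' Seeds are placed on a jittered hexagonal (centroidal-like) lattice; each
#' airspace takes the pixels nearest its seed among those it owns (strictly
#' nearest-seed pixels with a half-septum margin to the bisector), so per-
#' airspace areas are controlled exactly and septa arise as thickened region
#' boundaries. Slices are generated independently (the analysis chain is
#' strictly per-slice) with a per-slice lognormal size factor.
#'
#' All randomness flows from `spec$seed`; two calls with the same spec give
#' bit-identical truths.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with fields:
#'   `label_map` (integer array; 0 = tissue/septa, -1 = outside parenchyma,
#'   -2 = flooded/atelectatic, k >= 1 = airspace id, ids unique across the
#'   stack), `airspaces` (data frame: id, slice, row, col, target_area, area,
#'   open), `pixels` (per-slice lists of region pixel indices ordered
#'   nearest-first from the seed), `closure_order` (per-slice derecruitment
#'   permutation), `parenchyma` and `flooded` logical arrays,
#'   `mechanism_state`, and the generating `spec`.
#' @export
generate_parenchyma_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_side
  r_vox <- spec$domain_radius * 1000 / vs
  s_vox <- spec$septal_thickness / vs
  d_vox <- spec$mean_airspace_diameter / vs

  # analytic capacity check (hexagonal packing bound)
  need <- spec$target_count * pi * ((d_vox + s_vox) / 2)^2
  avail <- 0.91 * (1 - spec$flooded_fraction) * pi * r_vox^2
  if (need > avail)
    stopf(paste0("infeasible packing: %d airspaces of ~%.3g um need %.3g mm^2 ",
                 "but the %.3g mm disc offers %.3g mm^2"),
          spec$target_count, spec$mean_airspace_diameter,
          need * (vs / 1000)^2, spec$domain_radius, avail * (vs / 1000)^2)

  n <- 2L * ceiling(r_vox) + 5L
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  parenchyma2d <- (rr - ctr)^2 + (cc - ctr)^2 <= r_vox^2

  lab <- array(0L, dim = c(n, n, spec$n_slices))
  pixels <- vector("list", spec$n_slices)
  closure_order <- vector("list", spec$n_slices)
  rows_list <- vector("list", spec$n_slices)

  with_seed(spec$seed, {
    flooded2d <- matrix(FALSE, n, n)
    if (spec$flooded_fraction > 0) {
      theta <- runif(1, 0, 2 * pi)
      proj <- (rr - ctr) * cos(theta) + (cc - ctr) * sin(theta)
      q <- quantile(proj[parenchyma2d], 1 - spec$flooded_fraction,
                    type = 1, names = FALSE)
      flooded2d <- parenchyma2d & proj > q
    }
    open2d <- parenchyma2d & !flooded2d
    # keep seeds away from the pleural boundary and the cap so regions are
    # only mildly clipped there
    dist_in <- as.matrix(EBImage::distmap(open2d))
    id_offset <- 0L
    for (s in seq_len(spec$n_slices)) {
      g <- exp(rnorm(1, 0, spec$slice_size_cv))
      d_slice <- d_vox * g
      seed_ok <- dist_in > d_slice / 2 + 0.5
      seeds <- place_seeds(seed_ok, spec$target_count, spec$lattice_jitter, spec)
      nsd <- nrow(seeds)
      diam <- d_slice * exp(rnorm(nsd, -spec$diameter_cv^2 / 2, spec$diameter_cv))
      a_target <- pmax(1L, as.integer(round(pi * (diam / 2)^2)))

      sl <- matrix(0L, n, n)
      sl[!parenchyma2d] <- -1L
      sl[flooded2d] <- -2L
      px <- vector("list", nsd)
      sdist <- as.matrix(stats::dist(seeds))
      rb_all <- ceiling(sqrt(a_target / pi)) + 3
      for (i in seq_len(nsd)) {
        rb <- rb_all[i]
        r0 <- max(1L, floor(seeds[i, 1] - rb)); r1 <- min(n, ceiling(seeds[i, 1] + rb))
        c0 <- max(1L, floor(seeds[i, 2] - rb)); c1 <- min(n, ceiling(seeds[i, 2] + rb))
        lr <- r0:r1; lc <- c0:c1
        di <- sqrt(outer((lr - seeds[i, 1])^2, (lc - seeds[i, 2])^2, "+"))
        nb <- which(sdist[i, ] <= rb + max(rb_all) + s_vox + 2 & seq_len(nsd) != i)
        djmin <- matrix(Inf, length(lr), length(lc))
        for (j in nb) {
          dj <- sqrt(outer((lr - seeds[j, 1])^2, (lc - seeds[j, 2])^2, "+"))
          djmin <- pmin(djmin, dj)
        }
        ok <- open2d[lr, lc] & di < djmin & (djmin - di) >= s_vox
        lin <- outer(lr, (lc - 1L) * n, "+")  # linear indices in the slice
        cand <- which(ok)
        cand <- cand[order(di[cand], lin[cand])]
        take <- lin[cand[seq_len(min(a_target[i], length(cand)))]]
        px[[i]] <- take
        sl[take] <- id_offset + i
      }
      pixels[[s]] <- px
      closure_order[[s]] <- sample.int(nsd)
      lab[, , s] <- sl
      rows_list[[s]] <- data.frame(
        id = id_offset + seq_len(nsd), slice = s,
        row = seeds[, 1], col = seeds[, 2],
        target_area = a_target,
        area = vapply(px, length, integer(1)),
        open = TRUE
      )
      id_offset <- id_offset + nsd
    }
  })

  structure(
    list(label_map = lab,
         airspaces = do.call(rbind, rows_list),
         pixels = pixels,
         closure_order = closure_order,
         parenchyma = array(parenchyma2d, dim = c(n, n, spec$n_slices)),
         flooded = array(flooded2d, dim = c(n, n, spec$n_slices)),
         mechanism_state = list(mechanism = "none", fraction = 0),
         spec = spec),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d slices, %d airspaces (%d open), mechanism %s (fraction %s)\n",
              x$spec$n_slices, nrow(x$airspaces), sum(x$airspaces$open),
              x$mechanism_state$mechanism,
              paste(signif(unique(x$mechanism_state$fraction), 3), collapse = "/")))
  invisible(x)
}

#' Parenchyma mask of a phantom
#'
#' The mask a manual segmentation would supply: the full parenchyma disc is
#' `included` (flooded regions are still inside the outline and are left for
#' [exclude_nonventilated()] to remove); nothing is pre-excluded.
#'
#' @param truth a [generate_parenchyma_truth()] result.
#' @return A [parenchyma_mask()].
#' @export
phantom_mask <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  parenchyma_mask(truth$parenchyma, voxel_side = truth$spec$voxel_side)
}

#' Apply a deflation mechanism to a phantom truth
#'
#' Implements the two classic deflation modes the study contrasts:
#' `"balloon"` (proportional shrinkage: every open airspace keeps its
#' identity and its area is scaled by `1 - fraction`, exactly, by trimming
#' its outermost pixels), `"derecruitment"` (whole-airspace closure: a seeded
#' random subset of `round(fraction * N)` airspaces per slice is filled with
#' tissue, survivors untouched), and `"mixed"` (both, with the fraction split
#' 50/50). The mechanisms `"shape_change"` and `"crumpling"` are reserved
#' names and not implemented. Closure order and pixel-trim order are fixed
#' at truth generation, so applying non-decreasing fractions to the same base
#' truth yields nested (physically consistent) deflation states.
#'
#' @param truth a `phantom_truth`.
#' @param mechanism one of `"none"`, `"balloon"`, `"derecruitment"`,
#'   `"mixed"` (plus the reserved names above).
#' @param fraction deflation fraction in `[0, 1]`; either a scalar or one
#'   value per slice.
#' @return A new `phantom_truth` with updated label map, areas, open flags
#'   and `mechanism_state`.
#' @export
apply_deflation <- function(truth, mechanism, fraction) {
  stopifnot(inherits(truth, "phantom_truth"))
  mechanism <- match.arg(mechanism, c("none", "balloon", "derecruitment",
                                      "mixed", "shape_change", "crumpling"))
  if (mechanism %in% c("shape_change", "crumpling"))
    stopf("mechanism '%s' is a reserved name and not implemented", mechanism)
  ns <- truth$spec$n_slices
  if (!length(fraction) %in% c(1L, ns))
    stopf("fraction must be a scalar or one value per slice")
  if (any(fraction < 0 | fraction > 1)) stopf("fraction must be in [0, 1]")
  f <- rep(fraction, length.out = ns)
  if (mechanism == "none" || all(f == 0)) return(truth)

  if (mechanism == "mixed") {
    out <- apply_deflation(truth, "balloon", f / 2)
    out <- apply_deflation(out, "derecruitment", f / 2)
    out$mechanism_state <- list(mechanism = "mixed", fraction = fraction)
    return(out)
  }

  out <- truth
  for (s in seq_len(ns)) {
    rows <- which(out$airspaces$slice == s)
    local_open <- out$airspaces$open[rows]
    if (mechanism == "balloon") {
      for (i in which(local_open)) {
        old <- out$pixels[[s]][[i]]
        n_new <- max(1L, as.integer(round(length(old) * (1 - f[s]))))
        if (n_new < length(old)) {
          drop <- old[(n_new + 1L):length(old)]
          out$label_map[, , s][drop] <- 0L
          out$pixels[[s]][[i]] <- old[seq_len(n_new)]
          out$airspaces$area[rows[i]] <- n_new
        }
      }
    } else {  # derecruitment
      n_close <- as.integer(round(f[s] * sum(local_open)))
      victims <- out$closure_order[[s]][out$closure_order[[s]] %in% which(local_open)]
      victims <- victims[seq_len(min(n_close, length(victims)))]
      for (i in victims) {
        out$label_map[, , s][out$pixels[[s]][[i]]] <- 0L
        out$pixels[[s]][[i]] <- integer(0)
        out$airspaces$area[rows[i]] <- 0L
        out$airspaces$open[rows[i]] <- FALSE
      }
    }
  }
  out$mechanism_state <- list(mechanism = mechanism, fraction = fraction)
  out
}

#' Render a phantom truth into a grayscale image stack
#'
#' Gas voxels are drawn at `gas_level`; septa, flooded regions and everything
#' outside the parenchyma at `tissue_level`. A phase-contrast-like fringe is
#' added at every gas--tissue boundary (the boundary gas voxel is darkened to
#' `gas_level - fringe_amplitude`, the adjacent tissue voxel brightened to
#' `tissue_level + fringe_amplitude`), then seeded zero-mean Gaussian noise
#' of sd `noise_sigma` is added and the stack is quantized to 16 bit. Values
#' pushed outside `[0, 65535]` are clipped; the clip count is recorded in the
#' returned stack (`n_clipped`) with a warning.
#'
#' @param truth a `phantom_truth`.
#' @param spec the rendering spec; defaults to the truth's own.
#' @param seed seed for the noise; defaults to `spec$seed + 101`.
#' @return An [image_stack()] with an extra `n_clipped` field.
#' @export
render_image <- function(truth, spec = truth$spec, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(seed)) seed <- spec$seed + 101L
  dm <- dim(truth$label_map)
  img <- array(spec$tissue_level, dim = dm)
  gas <- truth$label_map > 0L
  img[gas] <- spec$gas_level
  if (spec$fringe_amplitude > 0) {
    for (s in seq_len(dm[3])) {
      g <- gas[, , s]
      near_gas <- shift_any4(g)
      dark <- g & shift_any4(!g)        # gas voxels touching tissue
      bright <- !g & near_gas           # tissue voxels touching gas
      sl <- img[, , s]
      sl[dark] <- spec$gas_level - spec$fringe_amplitude
      sl[bright] <- spec$tissue_level + spec$fringe_amplitude
      img[, , s] <- sl
    }
  }
  if (spec$noise_sigma > 0)
    with_seed(seed, img <- img + rnorm(length(img), 0, spec$noise_sigma))
  img <- round(img)
  n_clipped <- sum(img < 0 | img > GRAY_MAX)
  if (n_clipped > 0) {
    warning(sprintf("%d voxels clipped to the 16-bit range", n_clipped))
    img[img < 0] <- 0
    img[img > GRAY_MAX] <- GRAY_MAX
  }
  out <- image_stack(img, spec$voxel_side)
  out$n_clipped <- n_clipped
  out
}

#' Generate a rendered decremental-PEEP phantom series
#'
#' Builds one base truth and applies the deflation mechanism cumulatively:
#' each pressure level's fraction is applied to the same base truth, so a
#' non-decreasing fraction schedule yields a physically nested deflation
#' sequence (the synthetic twin of a decremental-PEEP maneuver with the
#' nominal ladder 12/9/6/3/0 cmH2O). `level_scatter` perturbs the fraction
#' per slice (sd = `level_scatter * fraction`), reproducing the growing
#' between-slice scatter seen at low airway pressures; at fraction 0 the
#' scatter is zero by construction.
#'
#' @param spec a [phantom_spec()].
#' @param mechanism deflation mechanism, see [apply_deflation()].
#' @param peep_levels pressures (cmH2O), one per level.
#' @param fractions non-decreasing deflation fractions, one per level.
#' @param level_scatter relative per-slice scatter of the applied fraction.
#' @return An object of class `peep_series`: a list with one element per
#'   level, each holding `peep`, `fraction`, `image` ([image_stack()]),
#'   `truth` (`phantom_truth`) and `mask` ([parenchyma_mask()]).
#' @export
make_peep_series <- function(spec, mechanism, peep_levels, fractions,
                             level_scatter = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(peep_levels) != length(fractions))
    stopf("peep_levels and fractions must have the same length")
  if (any(fractions < 0 | fractions > 1)) stopf("fractions must be in [0, 1]")
  if (is.unsorted(fractions)) stopf("fractions must be non-decreasing")
  base <- generate_parenchyma_truth(spec)
  mask <- phantom_mask(base)
  levels <- lapply(seq_along(peep_levels), function(i) {
    f <- fractions[i]
    if (level_scatter > 0 && f > 0) {
      with_seed(spec$seed + 7000L + i,
                z <- rnorm(spec$n_slices))
      f <- pmin(0.95, pmax(0, fractions[i] * (1 + level_scatter * z)))
    }
    truth_i <- apply_deflation(base, mechanism, f)
    list(peep = peep_levels[i], fraction = fractions[i],
         image = render_image(truth_i, spec, seed = spec$seed + 500L + i),
         truth = truth_i, mask = mask)
  })
  structure(levels, class = "peep_series")
}

#' Ground-truth summaries of a phantom truth
#'
#' `truth_open_counts()` gives the number of open airspaces per slice;
#' `truth_mean_area()` the mean area (voxels) of open airspaces per slice.
#'
#' @param truth a `phantom_truth`.
#' @return A numeric vector with one value per slice.
#' @export
truth_open_counts <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  vapply(seq_len(truth$spec$n_slices), function(s)
    sum(truth$airspaces$open[truth$airspaces$slice == s]), numeric(1))
}

#' @rdname truth_open_counts
#' @export
truth_mean_area <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  vapply(seq_len(truth$spec$n_slices), function(s) {
    a <- truth$airspaces
    mean(a$area[a$slice == s & a$open])
  }, numeric(1))
}
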