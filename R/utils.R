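# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# micrometres -> voxels
um_to_vox <- function(um, voxel_side) um / voxel_side

# EBImage grayscale morphology operates on [0, 1]; wrap 16-bit-unit images
GRAY_MAX <- 65535

ebi_closing <- function(x, brush) {
  EBImage::closing(x / GRAY_MAX, brush) * GRAY_MAX
}

ebi_gblur <- function(x, sigma) {
  EBImage::gblur(x / GRAY_MAX, sigma = sigma, boundary = "replicate") * GRAY_MAX
}

disc_brush <- function(radius_vox) {
  EBImage::makeBrush(2L * as.integer(radius_vox) + 1L, shape = "disc")
}

# logical matrix of pixels 4-adjacent to a TRUE pixel of `m` (excluding m itself
# unless include_self); image border treated as FALSE outside
shift_any4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
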