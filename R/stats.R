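#' Study configuration
#'
#' Defaults mirror the decremental-PEEP protocol the package targets:
#' a nominal PEEP ladder of 12/9/6/3/0 cmH2O, the corresponding measured
#' airway pressures 12.4/9.6/6.8/4.1/1.1 cmH2O, 40 slices of 47.7 um voxels,
#' and alpha = 0.05. The regression regressor defaults to the measured PEEP
#' (the applied pressure actually seen by the lung); the nominal ladder is
#' available as an alternative.
#'
#' @param peep_nominal nominal PEEP levels (cmH2O).
#' @param peep_measured measured PEEP levels (cmH2O), same length.
#' @param alpha significance level in (0, 1).
#' @param regressor `"measured"` or `"nominal"`.
#' @param n_slices slices per stack.
#' @param voxel_side voxel side (um).
#' @param offsets ROI band inner edges (mm).
#' @param radii top-hat disc radii (voxels).
#' @param smooth_sigma Gaussian pre-smoothing sd (voxels).
#' @param min_separation minimum peak separation (um).
#' @param h_depth peak prominence threshold (grayscale units), or NULL for
#'   5% of the enhanced dynamic range.
#' @param min_region minimum excluded non-ventilated region (voxels).
#' @param deep_radius tissue depth (voxels) identifying solid non-aerated
#'   regions, see [exclude_nonventilated()].
#' @param max_hole largest interior hole filled during exclusion (voxels).
#' @return A list of class `study_config`.
#' @export
study_config <- function(peep_nominal = c(12, 9, 6, 3, 0),
                         peep_measured = c(12.4, 9.6, 6.8, 4.1, 1.1),
                         alpha = 0.05,
                         regressor = c("measured", "nominal"),
                         n_slices = 40, voxel_side = 47.7,
                         offsets = c(0, 2, 4),
                         radii = c(2, 3, 4, 6), smooth_sigma = 0.8,
                         min_separation = 110, h_depth = NULL,
                         min_region = 50, deep_radius = 20, max_hole = 4) {
  if (length(peep_nominal) != length(peep_measured))
    stopf("peep_nominal and peep_measured must have equal length")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  regressor <- match.arg(regressor)
  structure(list(peep_nominal = peep_nominal, peep_measured = peep_measured,
                 alpha = alpha, regressor = regressor,
                 n_slices = as.integer(n_slices), voxel_side = voxel_side,
                 offsets = offsets, radii = radii,
                 smooth_sigma = smooth_sigma,
                 min_separation = min_separation, h_depth = h_depth,
                 min_region = min_region, deep_radius = deep_radius,
                 max_hole = max_hole),
            class = "study_config")
}

#' Linear regression of an airspace metric on applied PEEP
#'
#' Ordinary least squares of the pooled per-slice observations of `ASdim` or
#' `ASnum` (one ROI) on the applied PEEP. Observations with undefined
#' response (slices where no airspace was detected leave ASdim missing) are
#' dropped and counted. Returns slope, intercept, R-squared and the
#' two-sided p-value of the slope.
#'
#' @param table a `study_table` from [pool_slices()], or its `observations`
#'   data frame.
#' @param response `"ASdim"` or `"ASnum"`.
#' @param roi `"ALL"`, `"SUB"`, `"MAN"` or `"COR"`.
#' @param regressor `"measured"` or `"nominal"` PEEP.
#' @return An object of class `peep_regression`: response, roi, regressor,
#'   `m` (slope), `k` (intercept), `m_se` (slope standard error),
#'   `r_squared`, `p_value`, `n`, `n_dropped`, plus the fitted `x`/`y`
#'   vectors (used by the F-test).
#' @export
fit_peep_regression <- function(table, response = c("ASdim", "ASnum"),
                                roi = c("ALL", "SUB", "MAN", "COR"),
                                regressor = c("measured", "nominal")) {
  obs <- if (inherits(table, "study_table")) table$observations else table
  response <- match.arg(response)
  roi <- match.arg(roi)
  regressor <- match.arg(regressor)
  obs <- obs[obs$roi == roi, , drop = FALSE]
  x <- if (regressor == "measured") obs$peep_measured else obs$peep_nominal
  y <- obs[[response]]
  ok <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 observations with a defined %s", response)
  if (var(x) == 0) stopf("all observations share one PEEP value; no regressor variance")
  fit <- lm(y ~ x)
  # a noiseless phantom can produce an exactly constant response; the slope
  # test is then degenerate (p = NaN) but the fit itself is well defined
  sm <- suppressWarnings(summary(fit))
  structure(list(response = response, roi = roi, regressor = regressor,
                 m = unname(coef(fit)[2]), k = unname(coef(fit)[1]),
                 m_se = unname(sm$coefficients[2, 2]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x), n_dropped = n_dropped, x = x, y = y),
            class = "peep_regression")
}

#' @export
print.peep_regression <- function(x, ...) {
  cat(sprintf("%s ~ PEEP (%s), ROI %s: m = %.4g, k = %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$response, x$regressor, x$roi, x$m, x$k, x$r_squared,
              x$p_value, x$n))
  invisible(x)
}

#' Compare two regressions with an extra-sum-of-squares F-test
#'
#' Tests whether two regression lines (e.g. the same metric in two ROIs)
#' differ, by comparing a common (single slope and intercept) model fitted to
#' the concatenated data against the two separate fits:
#' `F = ((RSS_common - RSS_separate) / 2) / (RSS_separate / (n - 4))` with
#' (2, n - 4) degrees of freedom. Both input regressions are required to be
#' individually significant at `alpha` (only significant regression
#' equations are compared), unless `check_significance = FALSE`.
#'
#' @param fit_a,fit_b `peep_regression` objects (they carry their data).
#' @param alpha significance level for the precondition.
#' @param check_significance enforce the precondition.
#' @return A list with `F`, `p_value`, `df`, and the three residual sums of
#'   squares.
#' @export
compare_regressions_ftest <- function(fit_a, fit_b, alpha = 0.05,
                                      check_significance = TRUE) {
  stopifnot(inherits(fit_a, "peep_regression"), inherits(fit_b, "peep_regression"))
  if (check_significance && (fit_a$p_value > alpha || fit_b$p_value > alpha))
    stopf("both regressions must be significant at alpha = %g to be compared",
          alpha)
  n <- fit_a$n + fit_b$n
  if (n - 4 <= 0) stopf("insufficient degrees of freedom (n = %d)", n)
  rss <- function(x, y) sum(lm(y ~ x)$residuals^2)
  rss_a <- rss(fit_a$x, fit_a$y)
  rss_b <- rss(fit_b$x, fit_b$y)
  rss_sep <- rss_a + rss_b
  rss_common <- rss(c(fit_a$x, fit_b$x), c(fit_a$y, fit_b$y))
  f <- ((rss_common - rss_sep) / 2) / (rss_sep / (n - 4))
  f <- max(f, 0)
  list(F = f, p_value = pf(f, 2, n - 4, lower.tail = FALSE),
       df = c(2, n - 4), rss_common = rss_common, rss_separate = rss_sep)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped (their count is
#' reported). For up to 15 effective pairs the p-value comes from the exact
#' permutation distribution of the positive-rank sum over all 2^n sign
#' assignments (ties handled exactly through midranks); above that, a normal
#' approximation with tie correction and continuity correction is used.
#' If all differences are zero, p = 1 with a degeneracy flag.
#'
#' @param a,b paired numeric vectors.
#' @param exact_max largest n for which the exact distribution is enumerated.
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_effective`, `n_zero`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 15) {
  if (length(a) != length(b)) stopf("a and b must be paired (equal length)")
  if (length(a) < 1) stopf("need at least one pair")
  d <- a - b
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                n_zero = n_zero, method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)  # all 2^n sign assignments
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= v + eps), mean(sums >= v - eps)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, p_value = p, n_effective = n, n_zero = n_zero,
       method = method, degenerate = FALSE)
}

#' Bonferroni correction
#'
#' For a family of `m` tests at family-wise level `alpha`, the per-test
#' threshold is `alpha / m`; a p-value exactly at the threshold is declared
#' significant (decision rule `<=`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise significance level.
#' @return A list with `threshold`, `significant` (logical vector),
#'   `p_adjusted` (`pmin(1, p * m)`), `m`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stopf("p_values must be non-empty")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p_values must all be in [0, 1]")
  m <- length(p_values)
  list(threshold = alpha / m, significant = p_values <= alpha / m,
       p_adjusted = pmin(1, p_values * m), m = m)
}

#' Published group means of the airspace metrics
#'
#' The per-PEEP group means and SDs of ASdim (voxels) and ASnum (units/mm^3)
#' reported by the original rabbit ARDS synchrotron study for the entire
#' slice and the three concentric ROIs, together with the printed regression
#' parameters. These serve as reference inputs: regressing the printed
#' subpleural ASdim means on the measured PEEP means reproduces the printed
#' subpleural slope.
#'
#' @return A data frame with columns response, roi, peep_nominal,
#'   peep_measured, mean, sd, m, k, r_squared.
#' @export
published_group_means <- function() {
  peep_n <- c(12, 9, 6, 3, 0)
  peep_m <- c(12.4, 9.6, 6.8, 4.1, 1.1)
  rows <- list(
    list("ASdim", "ALL", c(13.1, 11.1, 9, 8, 7.6),
         c(2.2, 4.3, 5.7, 5.5, 4.3), 0.55, 6.03, 0.21),
    list("ASdim", "SUB", c(13.6, 13, 10.9, 9.9, 9.4),
         c(1.8, 2.8, 4.1, 4.6, 3.6), 0.41, 8.54, 0.22),
    list("ASdim", "MAN", c(12.9, 11.2, 9.1, 7.9, 7.4),
         c(1.8, 3.5, 5.5, 5.4, 3.6), 0.55, 5.95, 0.27),
    list("ASdim", "COR", c(12.9, 9.1, 6.9, 6.3, 5.9),
         c(2.9, 5.9, 7.6, 6.9, 5.5), 0.68, 3.61, 0.21),
    list("ASnum", "ALL", c(188, 163.2, 145.2, 142.4, 146.4),
         c(52.0, 86.3, 92.3, 104.9, 96.7), 5.96, 116.41, 0.08),
    list("ASnum", "SUB", c(189.7, 174.9, 158.7, 160.4, 162.5),
         c(56.7, 93.3, 98.6, 114.1, 109.8), 4.85, 136.21, 0.05),
    list("ASnum", "MAN", c(193.0, 167.0, 152.3, 145.6, 149.7),
         c(55.5, 90.9, 96.6, 109.7, 100.2), 6.15, 120.16, 0.09),
    list("ASnum", "COR", c(181.2, 144.7, 124.6, 121.3, 127.1),
         c(55.5, 91.7, 99.8, 111.7, 99.1), 6.89, 92.86, 0.10)
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(response = r[[1]], roi = r[[2]], peep_nominal = peep_n,
               peep_measured = peep_m, mean = r[[3]], sd = r[[4]],
               m = r[[5]], k = r[[6]], r_squared = r[[7]])))
}
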