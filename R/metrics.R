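as_pixels <- function(x) {
  if (inherits(x, "bmode_image")) x$pixels else as.matrix(x)
}

check_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_invalid("images must have identical shapes")
}

#' Global structural similarity (SSIM)
#'
#' Whole-image SSIM computed from the global pixel means, variances and
#' covariance:
#' `(2 mu_a mu_b + k1)(2 cov + k2) / ((mu_a^2 + mu_b^2 + k1)(var_a + var_b + k2))`.
#' This is the single-statistic form (not the common 11x11 windowed mean
#' SSIM); a windowed variant is available via `window`. Stabilizers
#' default to `k1 = (0.01 L)^2`, `k2 = (0.03 L)^2` with `L = 255`.
#' Symmetric in its arguments; 1 for identical images.
#'
#' @param gt,x Images (matrices or `bmode_image`s) of identical shape.
#' @param k1,k2 Positive stabilizers.
#' @param L Pixel dynamic range.
#' @param window Odd window size for the non-default windowed mean SSIM;
#'   `NULL` (default) computes the global statistic.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(gt, x, k1 = (0.01 * L)^2, k2 = (0.03 * L)^2, L = 255,
                 window = NULL) {
  if (k1 <= 0 || k2 <= 0) stop_invalid("k1, k2 must be positive")
  a <- as_pixels(gt); b <- as_pixels(x)
  check_congruent(a, b)
  if (length(a) < 2L) stop_invalid("need >= 2 pixels")
  if (is.null(window)) return(ssim_stat(a, b, k1, k2))
  if (window %% 2 != 1L) stop_invalid("window must be odd")
  h <- (window - 1L) / 2L
  vals <- c()
  nr <- nrow(a); nc <- ncol(a)
  for (i in seq(1L + h, nr - h)) {
    for (j in seq(1L + h, nc - h)) {
      ii <- (i - h):(i + h); jj <- (j - h):(j + h)
      vals <- c(vals, ssim_stat(a[ii, jj], b[ii, jj], k1, k2))
    }
  }
  mean(vals)
}

ssim_stat <- function(a, b, k1, k2) {
  mu_a <- mean(a); mu_b <- mean(b)
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  cab <- stats::cov(as.vector(a), as.vector(b))
  ((2 * mu_a * mu_b + k1) * (2 * cab + k2)) /
    ((mu_a^2 + mu_b^2 + k1) * (va + vb + k2))
}

#' Mean squared error between two images
#' @param gt,x Images of identical M x N shape.
#' @return Mean of squared pixel differences (0 for a perfect match).
#' @export
mse <- function(gt, x) {
  a <- as_pixels(gt); b <- as_pixels(x)
  check_congruent(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `20 log10(i_max / sqrt(MSE))` in dB; the printed `Imax/MSE` form is
#' read as `Imax / sqrt(MSE)`, the standard definition consistent with the
#' factor 20. A perfect match returns `Inf`.
#'
#' @param gt,x Images of identical shape.
#' @param i_max Maximum possible pixel value (default 255).
#' @return PSNR in dB (`Inf` when `mse == 0`).
#' @export
psnr <- function(gt, x, i_max = 255) {
  if (i_max <= 0) stop_invalid("i_max must be positive")
  m <- mse(gt, x)
  if (m == 0) return(Inf)
  20 * log10(i_max / sqrt(m))
}

#' Full width at half maximum of a 1-D profile
#'
#' Locates the global maximum and the two half-maximum crossings nearest
#' it (linear interpolation between samples). Errors when the peak sits at
#' a boundary with no crossing on one side.
#'
#' @param profile Numeric vector with a positive global maximum.
#' @param spacing Sample spacing in mm.
#' @return FWHM in mm.
#' @export
fwhm <- function(profile, spacing) {
  p <- as.numeric(profile)
  if (max(p) <= 0) stop_invalid("profile must have a positive maximum")
  k <- which.max(p)
  half <- p[k] / 2
  left <- NA_real_
  if (k > 1) for (i in seq(k, 2, by = -1)) {
    if (p[i - 1] <= half && p[i] > half) {
      left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]) - 1
      break
    }
  }
  right <- NA_real_
  n <- length(p)
  if (k < n) for (i in seq(k, n - 1)) {
    if (p[i] > half && p[i + 1] <= half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1]) - 1
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop_invalid("no half-maximum crossing on one side (peak at boundary)")
  (right - left) * spacing
}

#' Intersection over union of two binary masks
#' @param a,b Logical matrices of identical shape.
#' @return `|a & b| / |a | b|` in \[0, 1\]; errors on an empty union.
#' @export
iou <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop_invalid("masks must have identical shapes")
  u <- sum(a | b)
  if (u == 0L) stop_invalid("empty union")
  sum(a & b) / u
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference `y - x`), 95% limits of agreement
#' (`bias +- 1.96 SD(diff)`), Pearson correlation, and the two-tailed
#' paired t-test p-value. Pearson r of a constant series is reported as
#' `NA` with `r_defined = FALSE` rather than a number.
#'
#' @param x,y Paired measurement vectors (length >= 2).
#' @return An `agreement_result` list: `bias`, `loa_low`, `loa_high`,
#'   `pearson_r`, `r_defined`, `t_p_value`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x, y must be paired")
  if (length(x) < 2L) stop_invalid("need >= 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  r_def <- sd(x) > 0 && sd(y) > 0
  r <- if (r_def) cor(x, y) else NA_real_
  # constant differences make the paired t statistic undefined
  p <- tryCatch(t.test(y, x, paired = TRUE)$p.value,
                error = function(e) NA_real_)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, pearson_r = r,
                 r_defined = r_def, t_p_value = p, n = length(x)),
            class = "agreement_result")
}

#' Power of a two-sample t-test
#'
#' Two-tailed two-sample t-test power with pooled SD via the noncentral t
#' distribution: effect size `d = delta / sd_pooled`, noncentrality
#' `d * sqrt(n/2)`, `df = 2n - 2`. Matches the conventional
#' two-independent-groups calculation; a paired alternative (interpreting
#' `sd1` as the SD of differences, `df = n - 1`, ncp `d sqrt(n)`) is
#' available with `paired = TRUE`.
#'
#' @param delta Minimum detectable mean difference (same units as SDs).
#' @param sd1,sd2 Group standard deviations (> 0).
#' @param n_per_group Sample size per group (>= 2).
#' @param alpha Two-tailed significance level in (0, 1).
#' @param paired Use the paired-test variant.
#' @return Power in \[0, 1\]; equals `alpha` when `delta = 0`.
#' @export
ttest_power <- function(delta, sd1, sd2 = sd1, n_per_group, alpha = 0.05,
                        paired = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  if (n_per_group < 2L) stop_invalid("n_per_group must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_invalid("SDs must be positive")
  n <- n_per_group
  if (paired) {
    ncp <- delta / sd1 * sqrt(n)
    df <- n - 1
  } else {
    sp <- sqrt((sd1^2 + sd2^2) / 2)
    ncp <- delta / sp * sqrt(n / 2)
    df <- 2 * n - 2
  }
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}

#' Batch image-pair evaluation
#'
#' Computes SSIM/MSE/PSNR of sparse inputs and (optionally) restored
#' predictions against the dense ground truth.
#'
#' @param dense,sparse Lists of images; `pred` optional list of restored
#'   images.
#' @param pred Optional list of predictions aligned with `dense`.
#' @return data.frame with columns `pair_id`, `ssim_in`, `mse_in`,
#'   `psnr_in` and, when `pred` is given, `ssim_pred`, `mse_pred`,
#'   `psnr_pred`.
#' @export
evaluate_pairs <- function(dense, sparse, pred = NULL) {
  n <- length(dense)
  stopifnot(length(sparse) == n, is.null(pred) || length(pred) == n)
  out <- data.frame(
    pair_id = seq_len(n),
    ssim_in = vapply(seq_len(n), function(i)
      ssim(dense[[i]], sparse[[i]]), numeric(1)),
    mse_in = vapply(seq_len(n), function(i)
      mse(dense[[i]], sparse[[i]]), numeric(1)),
    psnr_in = vapply(seq_len(n), function(i)
      psnr(dense[[i]], sparse[[i]]), numeric(1)))
  if (!is.null(pred)) {
    out$ssim_pred <- vapply(seq_len(n), function(i)
      ssim(dense[[i]], pred[[i]]), numeric(1))
    out$mse_pred <- vapply(seq_len(n), function(i)
      mse(dense[[i]], pred[[i]]), numeric(1))
    out$psnr_pred <- vapply(seq_len(n), function(i)
      psnr(dense[[i]], pred[[i]]), numeric(1))
  }
  out
}
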