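test_that("global SSIM matches hand evaluation and its identities", {
  set.seed(1)
  img <- matrix(runif(256, 0, 255), 16)
  expect_identical(ssim(img, img), 1)

  # four-pixel hand oracle: direct arithmetic on the printed formula
  gt <- matrix(c(0, 1, 1, 0), 2)
  x <- matrix(c(1, 0, 0, 1), 2)
  k1 <- 1e-4; k2 <- 9e-4
  mu_g <- mean(gt); mu_x <- mean(x)
  vg <- sum((gt - mu_g)^2) / 3; vx <- sum((x - mu_x)^2) / 3
  cov <- sum((gt - mu_g) * (x - mu_x)) / 3
  ref <- ((2 * mu_g * mu_x + k1) * (2 * cov + k2)) /
    ((mu_g^2 + mu_x^2 + k1) * (vg + vx + k2))
  expect_equal(ssim(gt, x, k1 = k1, k2 = k2, L = 1), ref)

  # symmetry and bounds on random pairs
  set.seed(2)
  for (i in 1:25) {
    a <- matrix(runif(64, 0, 255), 8)
    b <- matrix(runif(64, 0, 255), 8)
    s <- ssim(a, b)
    expect_equal(s, ssim(b, a))
    expect_gte(s, -1); expect_lte(s, 1)
    expect_gte(mse(a, b), 0)
  }
  expect_error(ssim(gt, matrix(0, 3, 3)), class = "sparus_validation_error")
  expect_error(ssim(gt, x, k1 = 0), class = "sparus_validation_error")
})

test_that("MSE is the mean squared pixel difference", {
  gt <- matrix(0, 2, 2)
  x <- matrix(c(2, 0, 0, 0), 2)
  expect_equal(mse(gt, x), 1.0)
  expect_equal(mse(x, gt), mse(gt, x))
  expect_equal(mse(x, x), 0)
  expect_error(mse(gt, matrix(0, 2, 3)), class = "sparus_validation_error")
})

test_that("PSNR follows 20 log10(Imax / sqrt(MSE))", {
  gt <- matrix(0, 2, 2); x <- matrix(1, 2, 2)  # mse = 1
  expect_equal(psnr(gt, x, 255), 20 * log10(255))
  expect_equal(psnr(gt, x, 510) - psnr(gt, x, 255), 20 * log10(2))
  expect_identical(psnr(x, x), Inf)
  expect_error(psnr(gt, x, 0), class = "sparus_validation_error")

  # consistency: PSNR strictly decreases as MSE increases
  vals <- sapply(c(0.5, 1, 2, 8), function(s)
    psnr(gt, matrix(s, 2, 2), 255))
  expect_true(all(diff(vals) < 0))
})

test_that("FWHM recovers known profile widths", {
  x <- seq(-6, 6, by = 0.05)
  g <- exp(-x^2 / 2)                       # sigma = 1 mm
  expect_equal(fwhm(g, 0.05), 2 * sqrt(2 * log(2)), tolerance = 0.01)
  expect_equal(fwhm(3.7 * g, 0.05), fwhm(g, 0.05))  # scale invariance

  box <- c(rep(0, 20), rep(1, 41), rep(0, 20))      # 2 mm wide at 0.05 mm
  expect_lt(abs(fwhm(box, 0.05) - 2), 0.05 + 1e-12)

  expect_error(fwhm(c(1, 0.8, 0.2), 0.05), class = "sparus_validation_error")
  expect_error(fwhm(rep(0, 5), 1), class = "sparus_validation_error")
})

test_that("IoU counts intersection over union", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(iou(a, b), 0)
  c_ <- matrix(FALSE, 4, 4); c_[1:2, 2:3] <- TRUE  # half-overlap squares
  expect_equal(iou(a, c_), 1 / 3)
  expect_error(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               class = "sparus_validation_error")
})

test_that("Bland-Altman agrees with direct arithmetic", {
  set.seed(4)
  x <- rnorm(10, 1.4, 0.3)
  y <- x + rnorm(10, 0.05, 0.1)
  res <- bland_altman(x, y)
  d <- y - x
  expect_equal(res$bias, mean(d), tolerance = 1e-12)
  expect_equal(res$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(res$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(res$pearson_r, cor(x, y), tolerance = 1e-12)
  expect_equal(res$t_p_value, t.test(y, x, paired = TRUE)$p.value)

  off <- bland_altman(x, x + 0.5)
  expect_equal(off$bias, 0.5)
  expect_equal(off$loa_low, off$loa_high)

  const <- bland_altman(rep(1, 5), rep(1, 5))
  expect_false(const$r_defined)
  expect_true(is.na(const$pearson_r))
  expect_equal(const$bias, 0)
  expect_error(bland_altman(1, 2), class = "sparus_validation_error")
})

test_that("t-test power behaves like the noncentral t model", {
  expect_equal(ttest_power(0, 0.38, 0.37, 10), 0.05, tolerance = 1e-10)

  # monotone in effect size and sample size
  p_delta <- sapply(c(0.2, 0.5, 1.0), ttest_power,
                    sd1 = 0.38, sd2 = 0.37, n_per_group = 10)
  expect_true(all(diff(p_delta) > 0))
  p_n <- sapply(c(4, 10, 30), function(n)
    ttest_power(0.5, 0.38, 0.37, n))
  expect_true(all(diff(p_n) > 0))

  # detectable-difference ordering across the sample-size sweep
  for (n in c(4, 10, 20, 40, 60)) {
    pw <- sapply(c(0.3, 0.5, 1.0), ttest_power,
                 sd1 = 0.38, sd2 = 0.37, n_per_group = n)
    expect_true(all(diff(pw) > 0))
  }

  # Monte-Carlo cross-check at modest replication
  set.seed(11)
  n <- 10; reps <- 20000
  rej <- replicate(reps, {
    g1 <- rnorm(n, 0, 0.38); g2 <- rnorm(n, 0.5, 0.37)
    t.test(g1, g2, var.equal = TRUE)$p.value < 0.05
  })
  expect_equal(ttest_power(0.5, 0.38, 0.37, 10), mean(rej),
               tolerance = 0.01)

  expect_error(ttest_power(0.5, 0.38, 0.37, 10, alpha = 1.2),
               class = "sparus_validation_error")
  expect_error(ttest_power(0.5, -1, 0.37, 10),
               class = "sparus_validation_error")
})

test_that("pair evaluation tabulates input and prediction metrics", {
  set.seed(6)
  dense <- lapply(1:3, function(i) matrix(runif(64, 0, 255), 8))
  sparse <- lapply(dense, function(d) d + matrix(rnorm(64, 0, 20), 8))
  pred <- lapply(dense, function(d) d + matrix(rnorm(64, 0, 5), 8))
  tab <- evaluate_pairs(dense, sparse, pred)
  expect_named(tab, c("pair_id", "ssim_in", "mse_in", "psnr_in",
                      "ssim_pred", "mse_pred", "psnr_pred"))
  expect_equal(tab$mse_in[2], mse(dense[[2]], sparse[[2]]))
  expect_true(all(tab$mse_pred < tab$mse_in))
})
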