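test_that("mse/mae match direct elementwise computation", {
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mae(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(1:4, 1:4), 0)
  withr::local_seed(1)
  a <- matrix(rnorm(30), 5, 6); b <- matrix(rnorm(30), 5, 6)
  acc_se <- 0; acc_ae <- 0
  for (i in seq_along(a)) {
    acc_se <- acc_se + (a[i] - b[i])^2
    acc_ae <- acc_ae + abs(a[i] - b[i])
  }
  expect_equal(mse(a, b), acc_se / 30, tolerance = 1e-12)
  expect_equal(mae(a, b), acc_ae / 30, tolerance = 1e-12)
  expect_equal(mse(a, b), mse(b, a))
  expect_equal(mae(a, b), mae(b, a))
  expect_error(mse(1:3, 1:4), "shape")
})

test_that("psnr follows its closed form and error scaling", {
  gt <- c(2, -1, 0.5, 1)
  test1 <- gt + 0.1
  expect_equal(psnr(gt, test1), 10 * log10(2^2 / 0.01))
  expect_identical(psnr(gt, gt), Inf)
  # halving the error raises PSNR by 10 log10(4)
  expect_equal(psnr(gt, gt + 0.05) - psnr(gt, test1), 10 * log10(4),
               tolerance = 1e-12)
  # strictly decreasing in MSE at fixed peak
  expect_gt(psnr(gt, gt + 0.01), psnr(gt, gt + 0.02))
})

test_that("ssim equals 1 for identical inputs and is negative for sign flips", {
  withr::local_seed(2)
  m <- matrix(rnorm(20 * 20), 20, 20)
  expect_equal(ssim(m, m), 1)
  # sign flips are punished: far below the self-similarity score (the strict
  # covariance-sign argument applies to global statistics — checked on the
  # short-input fallback below — not to windowed local means)
  centered <- m - mean(m)
  expect_lt(ssim(centered, -centered), 0.6)
  # near-symmetric: the dynamic range is taken from the first argument, so
  # swapping arguments changes only the stability constants
  m2 <- m + rnorm(400, sd = 0.1)
  expect_equal(ssim(m, m2), ssim(m2, m), tolerance = 0.02)
})

test_that("ssim matches a direct windowed evaluation on a 16 x 16 case", {
  withr::local_seed(3)
  gt <- matrix(rnorm(256), 16, 16)
  test <- gt + matrix(rnorm(256, sd = 0.3), 16, 16)
  # brute force: explicit double loop over valid 11 x 11 windows
  w1 <- exp(-((1:11) - 6)^2 / (2 * 1.5^2)); w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  L <- max(gt) - min(gt)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (i in 1:6) for (j in 1:6) {
    gw <- gt[i:(i + 10), j:(j + 10)]
    tw <- test[i:(i + 10), j:(j + 10)]
    mx <- sum(W * gw); my <- sum(W * tw)
    vx <- sum(W * gw^2) - mx^2; vy <- sum(W * tw^2) - my^2
    cxy <- sum(W * gw * tw) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(ssim(gt, test), mean(vals), tolerance = 1e-8)
})

test_that("ssim works on 1-D spectra and falls back below the window size", {
  withr::local_seed(4)
  s <- rnorm(89)
  expect_equal(ssim(s, s), 1)
  short <- rnorm(5)
  expect_equal(ssim(short, short), 1)
  expect_lt(ssim(short - mean(short), -(short - mean(short))), 0)
})

test_that("metric_report bundles all four metrics", {
  withr::local_seed(5)
  gt <- matrix(runif(15 * 15), 15, 15)
  rep1 <- metric_report(gt, gt + 0.01)
  expect_named(rep1, c("mse", "mae", "psnr_db", "ssim"))
  expect_equal(rep1$mse, 1e-4, tolerance = 1e-10)
})
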