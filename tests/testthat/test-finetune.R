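test_that("PCA reconstruction is exact for spanned subspaces", {
  withr::local_seed(1)
  u <- rnorm(40); v <- rnorm(12)
  rank1 <- outer(u, v) + matrix(0.5, 40, 12) # rank-1 after centering
  expect_equal(pca_denoise(rank1, 1), rank1, tolerance = 1e-10,
               ignore_attr = TRUE)
  x <- matrix(rnorm(40 * 12), 40, 12)
  expect_equal(pca_denoise(x, 12), x, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pca_denoise(x, 13), "exceeds")
})

test_that("PCA with the true rank denoises a low-rank signal", {
  withr::local_seed(2)
  scores <- matrix(rnorm(500 * 3), 500, 3)
  basis <- matrix(rnorm(3 * 30), 3, 30)
  clean <- scores %*% basis
  noisy <- clean + matrix(rnorm(500 * 30, sd = 0.2), 500, 30)
  den <- pca_denoise(noisy, 3)
  expect_lt(mse(den, clean), mse(noisy, clean))
})

test_that("explained variance of successive components is non-increasing", {
  withr::local_seed(3)
  x <- matrix(rnorm(100 * 20), 100, 20) %*% diag(seq(2, 0.1, length.out = 20))
  sdev <- attr(pca_denoise(x, 5), "sdev")
  expect_true(all(diff(sdev) <= 1e-12))
})

test_that("finetune update rule matches the closed-form trace", {
  # stub predictor adds a constant bias b; with a small threshold the first
  # adjustment uses scale 1.01 and the next input is z_ori - 0.01 * b
  n <- 10
  b <- 0.05
  z_ori <- seq(0.5, 1, length.out = n)
  pca_ref <- z_ori # reference equal to the original spectrum: MSE_REF = 0 is
  # degenerate, so perturb slightly
  pca_ref <- z_ori + 0.001
  seen_inputs <- list()
  stub <- function(lp, hp) {
    seen_inputs[[length(seen_inputs) + 1]] <<- drop(lp)
    lp + b
  }
  cfg <- finetune_config(max_iterations = 1, threshold_factor = 1e-6)
  res <- context_finetune(stub, z_ori, z_ori, pca_ref, cfg)
  expect_length(seen_inputs, 2)
  expect_equal(seen_inputs[[1]], z_ori)
  # MSE_DPDL = mean((b - 0.001)^2) > MSE_REF = 0.001^2 -> scale 1.01
  expect_equal(seen_inputs[[2]], z_ori - 0.01 * b, tolerance = 1e-12)
  expect_equal(res$iterations, 1)
  expect_equal(res$z, z_ori - 0.01 * b + b, tolerance = 1e-12)
})

test_that("scale 0.99 branch is taken when the prediction is too close", {
  z_ori <- rep(1, 5)
  pca_ref <- z_ori + 0.1 # far reference: MSE_REF = 0.01
  b <- 0.02 # prediction closer to the reference than MSE_REF
  seen <- list()
  stub <- function(lp, hp) { seen[[length(seen) + 1]] <<- drop(lp); lp + b }
  cfg <- finetune_config(max_iterations = 1, threshold_factor = 1e-9)
  context_finetune(stub, z_ori, z_ori, pca_ref, cfg)
  # MSE_DPDL = (0.1 - 0.02)^2 = 0.0064 < MSE_REF -> scale 0.99
  expect_equal(seen[[2]], z_ori + 0.0002, tolerance = 1e-12)
})

test_that("early exit performs exactly one prediction", {
  calls <- 0
  identity_stub <- function(lp, hp) { calls <<- calls + 1; lp }
  z <- runif(8)
  res <- context_finetune(identity_stub, z, z, z + 0.05,
                          finetune_config(threshold_factor = 10))
  expect_equal(calls, 1)
  expect_equal(res$iterations, 0)
  expect_equal(res$z, z)
})

test_that("the loop never exceeds max_iterations adjustments", {
  calls <- 0
  biased <- function(lp, hp) { calls <<- calls + 1; lp + 1 } # never converges
  z <- runif(8)
  res <- context_finetune(biased, z, z, z,
                          finetune_config(max_iterations = 5,
                                          threshold_factor = 1e-12))
  expect_equal(calls, 6) # initial prediction + 5 adjustment cycles
  expect_equal(res$iterations, 5)
})

test_that("non-finite predictions abort with a diagnostic", {
  bad <- function(lp, hp) lp * NaN
  z <- runif(8)
  expect_error(context_finetune(bad, z, z, z, finetune_config()),
               "non-finite")
})

test_that("denoise_volume applies the voxel pipeline and logs iterations", {
  sched <- small_schedule(21)
  m <- build_denoiser(model_config(input_len = 21, channels = c(4, 8)), seed = 1)
  withr::local_seed(4)
  lp <- array(runif(4 * 3 * 21, 0.5, 1), c(4, 3, 21))
  hp <- array(runif(4 * 3 * 21, 0.3, 1), c(4, 3, 21))
  den <- denoise_volume(m, lp, hp, finetune_config(n_components = 2))
  expect_equal(dim(den$denoised), dim(lp))
  expect_true(all(den$iterations <= 5))
  expect_equal(nrow(den$log), 12)
  expect_error(denoise_volume(m, lp, hp[, 1:2, ]), "dimensions differ")

  # anti-collapse: the output never equals the PCA reference on noisy input
  expect_gt(max(abs(den$denoised - den$pca)), 1e-6)

  # purity: identical voxels give identical outputs
  lp1 <- lp; hp1 <- hp
  for (i in 1:4) for (j in 1:3) { lp1[i, j, ] <- lp[1, 1, ]; hp1[i, j, ] <- hp[1, 1, ] }
  den1 <- denoise_volume(m, lp1, hp1, finetune_config(n_components = 2))
  expect_equal(den1$denoised[4, 3, ], den1$denoised[1, 1, ], tolerance = 1e-12)
})
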