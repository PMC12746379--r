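test_that("model preserves shape, handles zeros, and reports parameters", {
  m <- build_denoiser(model_config(input_len = 89), seed = 1)
  out <- predict(m, rep(0, 89), rep(0, 89))
  expect_length(out, 89)
  expect_true(all(is.finite(out)))
  lp <- matrix(rnorm(3 * 89), 3, 89)
  expect_equal(dim(predict(m, lp, lp)), c(3, 89))
  expect_gt(m$n_params, 1000)
  expect_error(predict(m, rep(0, 50), rep(0, 50)), "input_len")
  expect_error(model_config(input_len = 4))
})

test_that("initialization and inference are deterministic", {
  m1 <- build_denoiser(seed = 42)
  m2 <- build_denoiser(seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- build_denoiser(seed = 43)
  expect_false(identical(m1$params, m3$params))
  x <- matrix(runif(2 * 89), 2, 89)
  expect_identical(predict(m1, x, x), predict(m1, x, x))
})

test_that("batch prediction preserves order and matches single calls", {
  m <- build_denoiser(seed = 1)
  withr::local_seed(5)
  lp <- matrix(runif(4 * 89), 4, 89)
  hp <- matrix(runif(4 * 89), 4, 89)
  batch <- predict(m, lp, hp)
  for (i in 1:4)
    expect_equal(batch[i, ], predict(m, lp[i, ], hp[i, ]), tolerance = 1e-12)
})

test_that("compiled forward pass agrees with the pure-R reference", {
  cfg <- model_config(input_len = 21, channels = c(3, 4))
  m <- build_denoiser(cfg, seed = 7)
  withr::local_seed(8)
  x <- dualcest:::denoiser_input(matrix(rnorm(3 * 21), 3, 21),
                                 matrix(rnorm(3 * 21), 3, 21))
  expect_equal(dualcest:::denoiser_forward(m$params, cfg, x)$pred,
               dualcest:::denoiser_forward_ref(m$params, cfg, x)$pred,
               tolerance = 1e-12)
  # even input length (no padding branch)
  cfg2 <- model_config(input_len = 20, channels = c(3, 4))
  m2 <- build_denoiser(cfg2, seed = 7)
  x2 <- dualcest:::denoiser_input(matrix(rnorm(2 * 20), 2, 20),
                                  matrix(rnorm(2 * 20), 2, 20))
  expect_equal(dualcest:::denoiser_forward(m2$params, cfg2, x2)$pred,
               dualcest:::denoiser_forward_ref(m2$params, cfg2, x2)$pred,
               tolerance = 1e-12)
})

test_that("backward pass matches finite differences", {
  cfg <- model_config(input_len = 21, channels = c(3, 4))
  m <- build_denoiser(cfg, seed = 7)
  withr::local_seed(9)
  x <- dualcest:::denoiser_input(matrix(rnorm(2 * 21), 2, 21),
                                 matrix(rnorm(2 * 21), 2, 21))
  y <- matrix(rnorm(2 * 21), 2, 21)
  loss_of <- function(p) mean((dualcest:::denoiser_forward(p, cfg, x)$pred - y)^2)
  fw <- dualcest:::denoiser_forward(m$params, cfg, x, keep_cache = TRUE)
  g <- dualcest:::denoiser_backward(m$params, fw$cache,
                                    2 * (fw$pred - y) / length(y), cfg)
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (i in idx) {
      p2 <- m$params
      p2[[nm]][i] <- p2[[nm]][i] + 1e-6
      numeric_grad <- (loss_of(p2) - loss_of(m$params)) / 1e-6
      expect_equal(g[[nm]][i], numeric_grad, tolerance = 1e-3)
    }
  }
})

test_that("training respects the 80/20 split and reduces the loss", {
  sched <- small_schedule(21)
  pairs <- generate_training_pairs(list(amide_system(), water_only_system()),
                                   noise_levels = 0, b0_shifts_ppm = c(-0.2, 0, 0.2),
                                   b1_scales = c(0.9, 1), seed = 1,
                                   schedule = sched)
  # replicate rows to reach 100 pairs
  idx <- rep(seq_len(nrow(pairs$lp_noisy)), length.out = 100)
  for (f in c("lp_noisy", "hp_noisy", "lp_clean")) pairs[[f]] <- pairs[[f]][idx, ]
  pairs$meta <- pairs$meta[idx, ]
  pairs <- prepare_features(pairs)
  m <- build_denoiser(model_config(input_len = 21, channels = c(8, 16)), seed = 2)
  m <- train_denoiser(m, pairs, train_config(epochs = 50, learning_rate = 1e-3,
                                             batch_size = 32, seed = 3))
  expect_equal(m$n_train, 80)
  expect_equal(m$n_val, 20)
  expect_lt(m$history$train_loss[50], m$history$train_loss[1])
  expect_true(m$trained)
})

test_that("training errors on unprepared or degenerate inputs", {
  pairs <- generate_training_pairs(list(amide_system()), noise_levels = 0.025,
                                   b0_shifts_ppm = 0, b1_scales = 1,
                                   schedule = small_schedule(21))
  m <- build_denoiser(model_config(input_len = 21), seed = 1)
  expect_error(train_denoiser(m, pairs), "hp_transformed")
  pairs <- prepare_features(pairs)
  one <- pairs
  for (f in c("lp_noisy", "hp_noisy", "lp_clean", "hp_transformed"))
    one[[f]] <- one[[f]][1, , drop = FALSE]
  expect_error(train_denoiser(m, one), "at least 2")
})

test_that("a trained model denoises held-out spectra", {
  sched <- build_offset_schedule()
  train_pairs <- prepare_features(generate_training_pairs(
    training_grid(12, seed = 21), noise_levels = 0.025, seed = 22,
    schedule = sched))
  m <- build_denoiser(model_config(channels = c(16, 32)), seed = 23)
  m <- train_denoiser(m, train_pairs,
                      train_config(learning_rate = 3e-3, epochs = 80,
                                   batch_size = 64, seed = 24))
  held_out <- prepare_features(generate_training_pairs(
    training_grid(4, seed = 31), noise_levels = 0.025, seed = 32,
    schedule = sched))
  pred <- predict(m, held_out$lp_noisy, held_out$hp_transformed)
  expect_lt(mse(pred, held_out$lp_clean), mse(held_out$lp_noisy, held_out$lp_clean))
})
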