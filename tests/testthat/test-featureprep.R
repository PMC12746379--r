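test_that("single-window transform reproduces the hand-worked block example", {
  # block of 3: out = hp - mean(hp) + mean(lp) = [2,3,4] - 3 + 1
  expect_equal(transform_single_window(c(1, 1, 1), c(2, 3, 4), 3, 0),
               c(0, 1, 2))
})

test_that("transform is the identity when hp equals lp", {
  withr::local_seed(1)
  lp <- runif(89)
  for (w in list(c(3, 0), c(3, 1), c(5, 0), c(5, 2)))
    expect_equal(transform_single_window(lp, lp, w[1], w[2]), lp)
  expect_equal(build_transformed_hp(lp, lp), lp)
})

test_that("constant spectra collapse to the lp constant", {
  out <- transform_single_window(rep(0.7, 20), rep(0.2, 20), 5, 2)
  expect_equal(out, rep(0.7, 20))
})

test_that("shift-0 transforms conserve the lp block means", {
  withr::local_seed(2)
  lp <- runif(89); hp <- runif(89)
  for (len in c(3, 5)) {
    out <- transform_single_window(lp, hp, len, 0)
    starts <- seq(1, 89, by = len)
    for (s in starts) {
      idx <- s:min(s + len - 1, 89)
      expect_equal(mean(out[idx]), mean(lp[idx]), tolerance = 1e-12)
    }
  }
})

test_that("transform is affine-equivariant", {
  withr::local_seed(3)
  lp <- runif(30); hp <- runif(30)
  a <- 2.5; c0 <- -0.3
  expect_equal(build_transformed_hp(a * lp + c0, a * hp + c0),
               a * build_transformed_hp(lp, hp) + c0, tolerance = 1e-12)
})

test_that("linear hp over constant lp gives per-block means equal to lp", {
  n <- 30
  hp <- 0.02 * seq_len(n) # slope s
  lp <- rep(0.8, n)
  out <- transform_single_window(lp, hp, 3, 0)
  # closed form: within each block, out = lp + s * (pos - mean(pos))
  blocks <- split(seq_len(n), rep(seq_len(10), each = 3))
  for (b in blocks) {
    expect_equal(mean(out[b]), 0.8, tolerance = 1e-12)
    expect_equal(out[b], 0.8 + 0.02 * (b - mean(b)), tolerance = 1e-12)
  }
})

test_that("length mismatch and window pre-conditions error", {
  expect_error(transform_single_window(1:3, 1:4, 3, 0), "mismatch")
  expect_error(transform_single_window(1:6, 1:6, 3, 3))
  # shorter than the window: whole spectrum is one block
  expect_equal(transform_single_window(c(1, 2), c(5, 7), 5, 0),
               c(5, 7) - 6 + 1.5)
})

test_that("feature angle is the normalized OLS slope", {
  offs <- seq(3, 4.5, by = 0.125)
  flat <- rep(0.9, length(offs))
  expect_equal(feature_angle(flat, offs, c(3.5, 4)), 0)
  vals <- 0.5 + 0.3 * offs
  s1 <- feature_angle(vals, offs, c(3.5, 4))
  expect_equal(s1, 0.3)
  expect_equal(feature_angle(vals, offs, c(3.5, 4), normalizer = s1), 1)
  # doubling the deviations from the in-range mean doubles the slope
  sel <- offs >= 3.5 & offs <= 4
  vals2 <- vals
  vals2[sel] <- mean(vals[sel]) + 2 * (vals[sel] - mean(vals[sel]))
  expect_equal(feature_angle(vals2, offs, c(3.5, 4), normalizer = s1), 2)
  expect_error(feature_angle(vals, offs, c(4.9, 5.1)), "fewer than 2")
})

test_that("feature-angle Monte Carlo: zero noise collapses the spread", {
  sched <- build_offset_schedule()
  sys <- amide_system()
  lp <- simulate_zspectrum(sys, 0.25, sched)
  hp <- simulate_zspectrum(sys, 1, sched)
  fa0 <- monte_carlo_feature_angle(lp, hp, noise_level = 0, n_reps = 5)
  expect_equal(fa0$std, rep(0, 3))
  expect_equal(fa0$mean[fa0$spectrum == "lp"], 1) # clean LP defines the unit
})

test_that("mean Monte-Carlo angle is unbiased for the clean angle", {
  sched <- build_offset_schedule()
  sys <- amide_system()
  lp <- simulate_zspectrum(sys, 0.25, sched)
  hp <- simulate_zspectrum(sys, 1, sched)
  fa <- monte_carlo_feature_angle(lp, hp, noise_level = 0.03, n_reps = 2000,
                                  seed = 11)
  lp_row <- fa[fa$spectrum == "lp", ]
  se <- lp_row$std / sqrt(2000)
  expect_lt(abs(lp_row$mean - 1), 3 * se)
})
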