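test_that("control normalization gives exactly 1 at the control offset", {
  sched <- offset_schedule(c(-2, 0, 2, 500), control_ppm = 500)
  for (sys in list(water_only_system(), amide_system())) {
    z <- simulate_zspectrum(sys, 0.5, sched)
    expect_equal(z$values[sched$offsets_ppm == 500], 1)
  }
})

test_that("pure direct saturation is symmetric about water", {
  z <- simulate_zspectrum(water_only_system(), 0.25)
  expect_equal(z$values, rev(z$values), tolerance = 1e-12)
})

test_that("direct water saturation deepens monotonically with power", {
  sched <- offset_schedule(c(-1, 0, 1))
  z0 <- vapply(c(0.25, 0.5, 1, 2), function(p)
    simulate_zspectrum(water_only_system(), p, sched)$values[2], numeric(1))
  expect_true(all(diff(z0) < 0))
})

test_that("CEST dip at the solute offset is deeper at high power", {
  sched <- offset_schedule(c(0, 3.5))
  sys <- amide_system()
  dip <- function(p) 1 - simulate_zspectrum(sys, p, sched)$values[2]
  expect_gt(dip(1), dip(0.25))
})

test_that("matrix-exponential propagation matches stiff ODE integration", {
  # a light spot check; the acceptance suite runs the full three-system version
  sched <- offset_schedule(c(-1.2, 2.1, 3.5))
  withr::local_seed(42)
  sys <- random_four_pool()
  z <- simulate_zspectrum(sys, 1, sched)
  z_ode <- oracle_zspectrum(sys, 1, sched)
  expect_equal(z$values, z_ode, tolerance = 1e-6)
})

test_that("propagation matches fixed-step RK4 on a non-stiff system", {
  sys <- pool_system(
    water = pool(0, 1, 0, 1.7, 0.07),
    solutes = list(pool(3.5, 0.002, 50, 1.5, 0.01))
  )
  sched <- offset_schedule(c(0.5, 3.5))
  z <- simulate_zspectrum(sys, 0.5, sched)
  pools <- dualcest:::pools_matrix(sys, 4.7)
  p2r <- dualcest:::ppm_to_rad(4.7)
  w1 <- 0.5 * dualcest:::uT_to_rad()
  # fixed-step explicit integration cannot reach the 500-ppm control (the
  # transverse precession there is far beyond its stability limit), so
  # compare the offset-to-offset ratio, in which the control cancels
  m1 <- oracle_rk4_mz(pools, sched$offsets_ppm[1] * p2r, w1, 5)
  m2 <- oracle_rk4_mz(pools, sched$offsets_ppm[2] * p2r, w1, 5)
  expect_equal(z$values[1] / z$values[2], m1 / m2, tolerance = 1e-6)
})

test_that("B0 shift moves the direct-saturation dip and B1 scales the power", {
  sched <- build_offset_schedule()
  sys <- water_only_system()
  z_shift <- simulate_zspectrum(sys, 0.25, sched,
                                sequence_params(B0_shift_ppm = 0.4))
  # water minimum should sit near -0.4 ppm after a +0.4 ppm shift of the axis
  expect_equal(sched$offsets_ppm[which.min(z_shift$values)], -0.375, tolerance = 0.15)
  z_b1 <- simulate_zspectrum(sys, 0.5, sched, sequence_params(B1_scale = 2))
  z_1uT <- simulate_zspectrum(sys, 1, sched)
  expect_equal(z_b1$values, z_1uT$values, tolerance = 1e-12)
})

test_that("invalid pool parameters are rejected by the compiled core", {
  sys <- amide_system()
  m <- dualcest:::pools_matrix(sys, 4.7)
  m[2, 4] <- -0.1
  expect_error(dualcest:::bm_zspectrum_cpp(c(0), m, 100, 5, 1e5), "negative")
  m[2, 4] <- NaN
  expect_error(dualcest:::bm_zspectrum_cpp(c(0), m, 100, 5, 1e5), "non-finite")
})
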