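sched <- build_offset_schedule()

two_pool_spectrum <- function(water_A = 0.85, water_w0 = 0.05, water_G = 1.8,
                              mt_A = 0.12, mt_w0 = -2.4, mt_G = 40,
                              offsets = sched$offsets_ppm) {
  1 - lorentzian(offsets, water_A, water_w0, water_G) -
    lorentzian(offsets, mt_A, mt_w0, mt_G)
}

test_that("two-pool parameters are recovered to 1e-4 relative", {
  truth <- c(water_A = 0.85, water_w0 = 0.05, water_G = 1.8,
             mt_A = 0.12, mt_w0 = -2.4, mt_G = 40)
  z <- do.call(two_pool_spectrum, as.list(truth))
  fit <- fit_reference(z, sched$offsets_ppm)
  expect_true(fit$converged)
  est <- c(fit$water$amplitude, fit$water$center_ppm, fit$water$fwhm_ppm,
           fit$mt$amplitude, fit$mt$center_ppm, fit$mt$fwhm_ppm)
  expect_equal(unname(est), unname(truth), tolerance = 1e-4)
  expect_equal(fit$reference, z, tolerance = 1e-6)
})

test_that("zero MT amplitude is recovered as (near) zero", {
  z <- two_pool_spectrum(mt_A = 0)
  fit <- fit_reference(z, sched$offsets_ppm)
  expect_true(fit$converged)
  expect_lte(fit$mt$amplitude, 1e-3)
})

test_that("the reference fit ignores CEST-range offsets by construction", {
  z <- two_pool_spectrum()
  fit1 <- fit_reference(z, sched$offsets_ppm)
  z2 <- z
  z2[sched$offsets_ppm == 3.5] <- z2[sched$offsets_ppm == 3.5] - 0.2
  fit2 <- fit_reference(z2, sched$offsets_ppm)
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-12)
})

test_that("AREX formula: identity, substitution, linearity", {
  expect_equal(arex(c(0.9, 0.8), c(0.9, 0.8), 1.3), c(0, 0))
  expect_equal(arex(0.5, 0.8, 1), 0.75)
  x <- arex(c(0.6, 0.7), c(0.8, 0.9), 1)
  expect_equal(arex(c(0.6, 0.7), c(0.8, 0.9), 2), 2 * x)
  expect_warning(out <- arex(c(0.5, 0), c(0.8, 0.8), 1), "nonpositive")
  expect_true(is.nan(out[2]))
})

test_that("peak maps take the window maximum voxel by voxel", {
  offs <- seq(-4, 4, by = 0.25)
  vol <- array(0, c(2, 2, length(offs)))
  vol[1, 1, which.min(abs(offs - 3.5))] <- 0.7
  maps <- peak_maps(vol, offs)
  expect_equal(maps$apt[1, 1], 0.7)
  expect_equal(maps$apt[2, 2], 0)
  expect_equal(maps$noe_m3.5, matrix(0, 2, 2))
  expect_error(peak_maps(vol, offs, windows = list(far = c(20, 21))),
               "no offsets")
  td <- tidy(maps)
  expect_equal(nrow(td), 5 * 4)
})

test_that("APT peak amplitude rises monotonically with amide fraction", {
  fracs <- seq(0.0005, 0.0045, length.out = 5)
  peaks <- vapply(fracs, function(f) {
    sys <- amide_system(f_amide = f)
    z <- simulate_zspectrum(sys, 0.25, sched)
    ld <- ld_analysis(z, R1w_per_s = sys$R1w_per_s)
    ld$peaks[["apt"]]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("AREX is approximately additive for dilute solutes", {
  base <- function(solutes) pool_system(
    water = pool(0, 1, 0, 1.7, 0.07), solutes = solutes)
  sA <- pool(3.5, 0.001, 50, 1.5, 0.002)
  sB <- pool(-3.5, 0.002, 20, 1.3, 0.002)
  z_of <- function(sys) simulate_zspectrum(sys, 0.25, sched)
  ld_of <- function(sys) ld_analysis(z_of(sys), R1w_per_s = 1 / 1.7)$arex_spectrum
  axA <- ld_of(base(list(sA)))
  axB <- ld_of(base(list(sB)))
  axAB <- ld_of(base(list(sA, sB)))
  iA <- which.min(abs(sched$offsets_ppm - 3.5))
  iB <- which.min(abs(sched$offsets_ppm + 3.5))
  expect_equal(axAB[iA], axA[iA] + axB[iA], tolerance = 0.1)
  expect_equal(axAB[iB], axA[iB] + axB[iB], tolerance = 0.1)
})

test_that("quantify_volume flags failed voxels instead of erroring", {
  offs <- sched$offsets_ppm
  vol <- array(NA_real_, c(1, 2, length(offs)))
  vol[1, 1, ] <- two_pool_spectrum()
  vol[1, 2, ] <- NaN # unfittable voxel
  q <- quantify_volume(vol, offs, r1w_map = 1)
  expect_equal(q$n_failed, 1L)
  expect_true(all(is.nan(q$arex[1, 2, ])))
  expect_false(anyNA(q$arex[1, 1, ]))
})
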