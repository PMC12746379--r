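#' Random spin systems for training-set generation
#'
#' Draws generic four-pool (water + two solutes + MT) systems spanning slow to
#' fast exchange, so the denoiser learns Z-spectral structure in general
#' rather than any fixed tissue. Solute offsets are sampled uniformly on
#' ±4 ppm, exchange rates log-uniformly on 20–5000 1/s, proton fractions on
#' 5e-4 to 5e-3, the MT fraction on 0.03–0.12, water T1 on 1–2.5 s and water
#' T2 on 40–120 ms.
#'
#' @param n_systems Number of systems to draw.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list of [pool_system()] objects.
#' @export
training_grid <- function(n_systems, seed = 1L) {
  stopifnot(n_systems >= 1)
  withr::local_seed(seed)
  lapply(seq_len(n_systems), function(i) {
    water_T1 <- runif(1, 1, 2.5)
    water_T2 <- runif(1, 0.04, 0.12)
    solutes <- lapply(1:2, function(j) {
      pool(offset_ppm = runif(1, -4, 4),
           fraction = runif(1, 5e-4, 5e-3),
           exchange_rate_per_s = exp(runif(1, log(20), log(5000))),
           T1_s = 1.5,
           T2_s = exp(runif(1, log(2e-3), log(2e-2))))
    })
    mt <- pool(offset_ppm = -2.5, fraction = runif(1, 0.03, 0.12),
               exchange_rate_per_s = runif(1, 20, 60), T1_s = 1.3, T2_s = 1e-5)
    pool_system(water = pool(0, 1, 0, water_T1, water_T2),
                solutes = solutes, mt = mt)
  })
}

#' Generate dual-power training pairs
#'
#' For every combination of spin system, noise level, B0 shift and B1 scale,
#' simulates the low-power (LP) and high-power (HP) Z-spectra under the
#' miscalibrated acquisition, adds independent Gaussian noise (same standard
#' deviation, as a fraction of the control signal, for both powers), and pairs
#' them with the clean LP spectrum simulated at B0 shift 0 and B1 scale 1 —
#' the regression target.
#'
#' Defaults are the study conditions: noise levels 2.5% and 3%, B0 shifts
#' 0/±0.2/±0.4 ppm, B1 scales 0.8–1.2, powers 0.25 and 1 µT, so each system
#' yields 2 × 5 × 5 = 50 pairs.
#'
#' @param systems List of [pool_system()]s (e.g. from [training_grid()]).
#' @param noise_levels Gaussian noise standard deviations (fraction of S0).
#' @param b0_shifts_ppm Additive B0 offset errors, ppm.
#' @param b1_scales Multiplicative B1 scale factors.
#' @param powers_uT Length-2 vector `c(LP, HP)` in microtesla.
#' @param seed Master integer seed for all noise draws.
#' @param schedule An [offset_schedule()].
#' @param seq_params Base [sequence_params()] (its B0/B1 fields are overridden
#'   per combination).
#' @return A `dual_power_set`: matrices `lp_noisy`, `hp_noisy`, `lp_clean`
#'   (pairs × offsets), `hp_transformed` (filled by [prepare_features()]),
#'   the `schedule`, `powers_uT` and a `meta` tibble (one row per pair).
#' @export
generate_training_pairs <- function(systems,
                                    noise_levels = c(0.025, 0.03),
                                    b0_shifts_ppm = c(-0.4, -0.2, 0, 0.2, 0.4),
                                    b1_scales = c(0.8, 0.9, 1, 1.1, 1.2),
                                    powers_uT = c(0.25, 1),
                                    seed = 1L,
                                    schedule = build_offset_schedule(),
                                    seq_params = sequence_params()) {
  if (length(systems) == 0) stop("empty system grid")
  if (inherits(systems, "cest_pool_system")) systems <- list(systems)
  stopifnot(length(powers_uT) == 2, powers_uT[1] < powers_uT[2])
  n_off <- length(schedule)
  combos <- tidyr::expand_grid(
    system_id = seq_along(systems),
    b0_shift_ppm = b0_shifts_ppm,
    b1_scale = b1_scales,
    noise_level = noise_levels
  )

  # clean spectra per (system, b0, b1, power); noise applied afterwards
  sim_combos <- dplyr::distinct(combos, .data$system_id, .data$b0_shift_ppm,
                                .data$b1_scale)
  sim_lp <- matrix(NA_real_, nrow(sim_combos), n_off)
  sim_hp <- matrix(NA_real_, nrow(sim_combos), n_off)
  for (i in seq_len(nrow(sim_combos))) {
    sp <- seq_params
    sp$B0_shift_ppm <- sim_combos$b0_shift_ppm[i]
    sp$B1_scale <- sim_combos$b1_scale[i]
    sys_i <- systems[[sim_combos$system_id[i]]]
    sim_lp[i, ] <- simulate_zspectrum(sys_i, powers_uT[1], schedule, sp)$values
    sim_hp[i, ] <- simulate_zspectrum(sys_i, powers_uT[2], schedule, sp)$values
  }
  clean_lp_by_system <- t(vapply(systems, function(s) {
    sp <- seq_params; sp$B0_shift_ppm <- 0; sp$B1_scale <- 1
    simulate_zspectrum(s, powers_uT[1], schedule, sp)$values
  }, numeric(n_off)))

  key <- paste(sim_combos$system_id, sim_combos$b0_shift_ppm, sim_combos$b1_scale)
  row_of <- match(paste(combos$system_id, combos$b0_shift_ppm, combos$b1_scale), key)

  n_pairs <- nrow(combos)
  withr::local_seed(seed)
  noise_lp <- matrix(rnorm(n_pairs * n_off), n_pairs, n_off) * combos$noise_level
  noise_hp <- matrix(rnorm(n_pairs * n_off), n_pairs, n_off) * combos$noise_level

  structure(list(
    lp_noisy = sim_lp[row_of, , drop = FALSE] + noise_lp,
    hp_noisy = sim_hp[row_of, , drop = FALSE] + noise_hp,
    lp_clean = clean_lp_by_system[combos$system_id, , drop = FALSE],
    hp_transformed = NULL,
    schedule = schedule,
    powers_uT = powers_uT,
    meta = tibble::as_tibble(combos)
  ), class = "dual_power_set")
}

#' Apply dual-power feature preparation to a training/inference set
#'
#' Fills the `hp_transformed` matrix of a `dual_power_set` by applying
#' [build_transformed_hp()] row by row.
#'
#' @param set A `dual_power_set`.
#' @param lengths Window lengths passed to [build_transformed_hp()].
#' @return The set with `hp_transformed` populated.
#' @export
prepare_features <- function(set, lengths = c(3, 5)) {
  stopifnot(inherits(set, "dual_power_set"))
  set$hp_transformed <- t(vapply(seq_len(nrow(set$lp_noisy)), function(i) {
    build_transformed_hp(set$lp_noisy[i, ], set$hp_noisy[i, ], lengths = lengths)
  }, numeric(ncol(set$lp_noisy))))
  set
}

#' @export
print.dual_power_set <- function(x, ...) {
  cat(sprintf("<dual_power_set> %d pairs x %d offsets, powers %.3g/%.3g uT%s\n",
              nrow(x$lp_noisy), ncol(x$lp_noisy), x$powers_uT[1], x$powers_uT[2],
              if (is.null(x$hp_transformed)) " (features not prepared)" else ""))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dual_power_set <- function(x, ...) {
  tibble(n_pairs = nrow(x$lp_noisy), n_offsets = ncol(x$lp_noisy),
         lp_uT = x$powers_uT[1], hp_uT = x$powers_uT[2],
         features_prepared = !is.null(x$hp_transformed))
}
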