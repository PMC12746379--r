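#' Parameter table for the brain-mimicking digital phantom
#'
#' A deterministic 25 × 25 voxel grid of seven-pool systems (amide 3.5 ppm,
#' amine 3 ppm, guanidine 2 ppm, water, NOE at −1.6 and −3.5 ppm, and MT)
#' with literature-typical 4.7 T tissue values: a "normal tissue" background,
#' a circular "tumor" region (elevated amide and water T1, reduced NOE and
#' MT), and smooth sinusoidal spatial modulation so parameters vary voxel to
#' voxel. The values are synthetic stand-ins chosen to mimic brain contrast.
#'
#' @param nx,ny Grid size before edge trimming.
#' @return A tibble with one row per voxel: `x`, `y`, `region`, water
#'   relaxation times and per-pool fraction/rate/T2 columns.
#' @export
phantom_param_table <- function(nx = 25, ny = 25) {
  stopifnot(nx >= 3, ny >= 3)
  grid <- tidyr::expand_grid(x = seq_len(nx), y = seq_len(ny))
  cx <- (nx + 1) / 2 + nx / 8
  cy <- (ny + 1) / 2 - ny / 8
  r <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)
  tumor <- r <= min(nx, ny) / 4.5
  # smooth +-12% modulation so the clean signal is not piecewise constant
  mod <- 1 + 0.12 * sin(2 * pi * grid$x / nx) * sin(2 * pi * grid$y / ny)

  tibble(
    x = grid$x, y = grid$y,
    region = ifelse(tumor, "tumor", "normal"),
    water_T1_s = ifelse(tumor, 2.1, 1.7) * (1 + 0.05 * (mod - 1)),
    water_T2_s = ifelse(tumor, 0.09, 0.07),
    amide_f = ifelse(tumor, 0.0017, 0.0012) * mod,
    amide_k = 50,
    amide_T2_s = 0.002,
    amine_f = 0.0025 * mod,
    amine_k = 2000,
    amine_T2_s = 0.002,
    guan_f = ifelse(tumor, 0.0009, 0.001) * mod,
    guan_k = 200,
    guan_T2_s = 0.005,
    noe16_f = ifelse(tumor, 0.0011, 0.0016) * mod,
    noe16_k = 10,
    noe16_T2_s = 0.002,
    noe35_f = ifelse(tumor, 0.0028, 0.004) * mod,
    noe35_k = 20,
    noe35_T2_s = 0.001,
    mt_f = ifelse(tumor, 0.05, 0.07) * mod,
    mt_k = 30,
    mt_T2_s = 1e-5
  )
}

# one row of the parameter table -> pool_system
phantom_row_system <- function(row) {
  pool_system(
    water = pool(0, 1, 0, row$water_T1_s, row$water_T2_s),
    solutes = list(
      pool(3.5, row$amide_f, row$amide_k, 1.5, row$amide_T2_s),
      pool(3.0, row$amine_f, row$amine_k, 1.5, row$amine_T2_s),
      pool(2.0, row$guan_f, row$guan_k, 1.5, row$guan_T2_s),
      pool(-1.6, row$noe16_f, row$noe16_k, 1.3, row$noe16_T2_s),
      pool(-3.5, row$noe35_f, row$noe35_k, 1.3, row$noe35_T2_s)
    ),
    mt = pool(-2.5, row$mt_f, row$mt_k, 1.3, row$mt_T2_s)
  )
}

#' Generate the digital phantom with ground truth
#'
#' Simulates, for every voxel of `param_table`, the clean LP Z-spectrum
#' (B0 shift 0, B1 scale 1 — the ground truth), and noisy LP/HP Z-spectra
#' under per-voxel B0 shifts and B1 scales drawn from small discrete sets,
#' with independent Gaussian noise per spectrum. One voxel is trimmed from
#' every edge to avoid edge effects, so a 25 × 25 table yields 23 × 23 stacks.
#'
#' Two independent LP noise realizations are returned; averaging them gives a
#' two-average LP acquisition for single-power baselines at the same
#' acquisition budget as one LP + one HP scan.
#'
#' @param param_table Tibble from [phantom_param_table()] (or same columns).
#' @param seed Integer seed controlling B0/B1 draws and all noise.
#' @param noise_level Gaussian noise sd as a fraction of S0 (default 2.5%).
#' @param b0_choices,b1_choices Discrete per-voxel B0 shift (ppm) / B1 scale sets.
#' @param powers_uT `c(LP, HP)` in microtesla.
#' @param schedule An [offset_schedule()].
#' @param seq_params Base [sequence_params()].
#' @return A `digital_phantom`: arrays `lp_noisy`, `lp_noisy_2`, `hp_noisy`,
#'   `lp_clean` of dim (nx−2, ny−2, n_offsets); matrices `b0_map`, `b1_map`,
#'   `r1w_map`; the trimmed `param_table`; `schedule`, `powers_uT`,
#'   `noise_level`, `seed`.
#' @export
generate_digital_phantom <- function(param_table = phantom_param_table(),
                                     seed = 1L,
                                     noise_level = 0.025,
                                     b0_choices = c(-0.3, 0, 0.3),
                                     b1_choices = c(0.85, 1, 1.15),
                                     powers_uT = c(0.25, 1),
                                     schedule = build_offset_schedule(),
                                     seq_params = sequence_params()) {
  nx <- max(param_table$x)
  ny <- max(param_table$y)
  if (nx < 3 || ny < 3) stop("phantom grid must be at least 3 x 3")
  stopifnot(nrow(param_table) == nx * ny)
  n_off <- length(schedule)

  withr::local_seed(seed)
  b0 <- sample(b0_choices, nx * ny, replace = TRUE)
  b1 <- sample(b1_choices, nx * ny, replace = TRUE)

  lp_clean <- matrix(NA_real_, nx * ny, n_off)
  lp_sim <- matrix(NA_real_, nx * ny, n_off)
  hp_sim <- matrix(NA_real_, nx * ny, n_off)
  for (i in seq_len(nx * ny)) {
    sys_i <- phantom_row_system(param_table[i, ])
    sp0 <- seq_params; sp0$B0_shift_ppm <- 0; sp0$B1_scale <- 1
    lp_clean[i, ] <- simulate_zspectrum(sys_i, powers_uT[1], schedule, sp0)$values
    sp <- seq_params; sp$B0_shift_ppm <- b0[i]; sp$B1_scale <- b1[i]
    lp_sim[i, ] <- simulate_zspectrum(sys_i, powers_uT[1], schedule, sp)$values
    hp_sim[i, ] <- simulate_zspectrum(sys_i, powers_uT[2], schedule, sp)$values
  }
  noise <- function() matrix(rnorm(nx * ny * n_off, sd = noise_level), nx * ny, n_off)
  lp_noisy <- lp_sim + noise()
  lp_noisy_2 <- lp_sim + noise()
  hp_noisy <- hp_sim + noise()

  keep <- param_table$x > 1 & param_table$x < nx & param_table$y > 1 & param_table$y < ny
  # param_table is expand_grid(x, y): y varies fastest; reorder so x is fastest,
  # matching R array filling order for the (x, y, offset) stacks
  ord <- order(param_table$y[keep], param_table$x[keep])
  stack_of <- function(m) {
    mm <- m[keep, , drop = FALSE][ord, , drop = FALSE]
    array(mm, c(nx - 2, ny - 2, n_off))
  }
  map_of <- function(v) matrix(v[keep][ord], nx - 2, ny - 2)

  trimmed <- param_table[keep, ][ord, ]
  structure(list(
    lp_noisy = stack_of(lp_noisy),
    lp_noisy_2 = stack_of(lp_noisy_2),
    hp_noisy = stack_of(hp_noisy),
    lp_clean = stack_of(lp_clean),
    b0_map = map_of(b0),
    b1_map = map_of(b1),
    r1w_map = map_of(1 / param_table$water_T1_s),
    param_table = trimmed,
    schedule = schedule,
    powers_uT = powers_uT,
    noise_level = noise_level,
    seed = seed
  ), class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$lp_noisy)
  cat(sprintf("<digital_phantom> %d x %d voxels x %d offsets, noise %.3g%%, powers %.3g/%.3g uT\n",
              d[1], d[2], d[3], 100 * x$noise_level, x$powers_uT[1], x$powers_uT[2]))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.digital_phantom <- function(x, ...) {
  d <- dim(x$lp_noisy)
  tibble(nx = d[1], ny = d[2], n_offsets = d[3],
         noise_level = x$noise_level, lp_uT = x$powers_uT[1],
         hp_uT = x$powers_uT[2], seed = x$seed)
}
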