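# Independent Bloch-McConnell oracle: the coupled ODEs are written out
# directly (no shared code with the package's generator construction) and
# integrated with deSolve's implicit Runge-Kutta solver (radau) at tight
# tolerances. The semisolid pool's very short T2 makes the system stiff AND
# the off-resonance transverse components oscillate at up to ~5000 rad/s, so
# naive fixed-step explicit integration (and even lsoda) is inadequate; a
# fixed-step RK4 cross-check is used for non-stiff solute-only systems.

oracle_rhs <- function(t, M, parms) {
  p <- parms$pools # rows: shift_rad, R1, R2, f, k (water first)
  w1 <- parms$w1
  dw <- parms$domega
  n <- nrow(p)
  dM <- numeric(3 * n)
  for (i in seq_len(n)) {
    xi <- 3 * i - 2; yi <- 3 * i - 1; zi <- 3 * i
    theta <- p[i, 1] - dw
    dM[xi] <- -p[i, 3] * M[xi] + theta * M[yi]
    dM[yi] <- -theta * M[xi] - p[i, 3] * M[yi] + w1 * M[zi]
    dM[zi] <- -w1 * M[yi] - p[i, 2] * (M[zi] - p[i, 4])
  }
  # exchange with water (pool 1)
  for (i in seq_len(n)[-1]) {
    k <- p[i, 5]
    kw <- p[i, 4] * k
    for (c in 0:2) {
      iw <- 1 + c; is <- 3 * i - 2 + c
      dM[is] <- dM[is] + kw * M[iw] - k * M[is]
      dM[iw] <- dM[iw] + k * M[is] - kw * M[iw]
    }
  }
  list(dM)
}

oracle_water_mz <- function(pools, domega_rad, w1_rad, t_sat) {
  n <- nrow(pools)
  M0 <- numeric(3 * n)
  M0[3 * seq_len(n)] <- pools[, 4]
  out <- deSolve::ode(y = M0, times = c(0, t_sat), func = oracle_rhs,
                      parms = list(pools = pools, w1 = w1_rad, domega = domega_rad),
                      method = "radau", rtol = 1e-8, atol = 1e-10,
                      maxsteps = 1e6)
  out[nrow(out), 1 + 3]
}

oracle_zspectrum <- function(system, power_uT, schedule,
                             seq_params = sequence_params()) {
  pools <- dualcest:::pools_matrix(system, seq_params$field_T)
  p2r <- dualcest:::ppm_to_rad(seq_params$field_T)
  w1 <- power_uT * seq_params$B1_scale * dualcest:::uT_to_rad()
  offs <- (schedule$offsets_ppm + seq_params$B0_shift_ppm) * p2r
  ctrl <- (schedule$control_ppm + seq_params$B0_shift_ppm) * p2r
  s0 <- oracle_water_mz(pools, ctrl, w1, seq_params$sat_duration_s)
  vapply(offs, function(d) oracle_water_mz(pools, d, w1, seq_params$sat_duration_s),
         numeric(1)) / s0
}

# fixed-step classic RK4 for non-stiff systems
oracle_rk4_mz <- function(pools, domega_rad, w1_rad, t_sat, dt = 2.5e-4) {
  n <- nrow(pools)
  M <- numeric(3 * n)
  M[3 * seq_len(n)] <- pools[, 4]
  parms <- list(pools = pools, w1 = w1_rad, domega = domega_rad)
  f <- function(M) oracle_rhs(0, M, parms)[[1]]
  steps <- ceiling(t_sat / dt)
  h <- t_sat / steps
  for (s in seq_len(steps)) {
    k1 <- f(M); k2 <- f(M + h / 2 * k1); k3 <- f(M + h / 2 * k2); k4 <- f(M + h * k3)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  M[3]
}
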