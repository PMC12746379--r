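#' Exchanging proton pools
#'
#' A pool is one compartment of the Bloch-McConnell system: water, a solute
#' (amide, amine, guanidine, NOE, ...) or the semisolid MT pool. Fractions are
#' proton fractions relative to water; exchange rates are pool-to-water rates
#' (the back rate follows from detailed balance).
#'
#' @param offset_ppm Chemical shift relative to water, ppm.
#' @param fraction Proton fraction relative to water (water itself is 1).
#' @param exchange_rate_per_s Exchange rate pool -> water, 1/s (0 for water).
#' @param T1_s,T2_s Longitudinal / transverse relaxation times, s.
#' @return A `cest_pool` object.
#' @export
pool <- function(offset_ppm, fraction, exchange_rate_per_s, T1_s, T2_s) {
  stopifnot(is.numeric(offset_ppm), is.finite(offset_ppm))
  if (!is.finite(fraction) || fraction < 0) stop("pool fraction must be >= 0")
  if (!is.finite(exchange_rate_per_s) || exchange_rate_per_s < 0)
    stop("exchange rate must be >= 0")
  if (!is.finite(T1_s) || T1_s <= 0) stop("T1 must be > 0")
  if (!is.finite(T2_s) || T2_s <= 0) stop("T2 must be > 0")
  if (T2_s > T1_s) stop("T2 must not exceed T1")
  structure(list(offset_ppm = offset_ppm, fraction = fraction,
                 exchange_rate_per_s = exchange_rate_per_s,
                 T1_s = T1_s, T2_s = T2_s),
            class = "cest_pool")
}

#' Multi-pool spin system
#'
#' Water plus any number of solute pools and an optional semisolid MT pool.
#' The MT pool is treated as an ordinary Bloch pool with a very short T2
#' (Lorentzian lineshape).
#'
#' @param water A [pool()] at 0 ppm with fraction 1 (exchange rate ignored).
#' @param solutes List of solute [pool()]s.
#' @param mt Optional MT [pool()], or `NULL`.
#' @return A `cest_pool_system`; `$R1w_per_s` is `1/water$T1_s`, the water
#'   longitudinal rate used by the AREX metric.
#' @examples
#' sys <- pool_system(
#'   water = pool(0, 1, 0, T1_s = 1.7, T2_s = 0.07),
#'   solutes = list(pool(3.5, 0.001, 50, 1.5, 0.002)),
#'   mt = pool(-2.5, 0.07, 30, 1.3, 1e-5)
#' )
#' @export
pool_system <- function(water, solutes = list(), mt = NULL) {
  stopifnot(inherits(water, "cest_pool"))
  if (water$offset_ppm != 0) stop("water pool must sit at 0 ppm")
  if (water$fraction != 1) stop("water pool fraction must be 1")
  if (length(solutes) && !all(vapply(solutes, inherits, TRUE, "cest_pool")))
    stop("solutes must be a list of pool() objects")
  if (!is.null(mt)) stopifnot(inherits(mt, "cest_pool"))
  structure(list(water = water, solutes = solutes, mt = mt,
                 R1w_per_s = 1 / water$T1_s),
            class = "cest_pool_system")
}

# 5-column matrix (shift rad/s, R1, R2, f, k) consumed by the compiled core;
# water first, then solutes, then MT.
pools_matrix <- function(system, field_T) {
  stopifnot(inherits(system, "cest_pool_system"))
  all_pools <- c(list(system$water), system$solutes,
                 if (!is.null(system$mt)) list(system$mt))
  m <- t(vapply(all_pools, function(p) {
    c(p$offset_ppm * ppm_to_rad(field_T), 1 / p$T1_s, 1 / p$T2_s,
      p$fraction, p$exchange_rate_per_s)
  }, numeric(5)))
  m[1, 4] <- 1  # water fraction
  m[1, 5] <- 0  # water carries no self-exchange column
  m
}

#' @export
print.cest_pool_system <- function(x, ...) {
  cat(sprintf("<cest_pool_system> water (T1 %.3g s, T2 %.3g s) + %d solute(s)%s\n",
              x$water$T1_s, x$water$T2_s, length(x$solutes),
              if (is.null(x$mt)) "" else " + MT"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cest_pool_system <- function(x, ...) {
  all_pools <- c(list(water = x$water),
                 setNames(x$solutes, paste0("solute", seq_along(x$solutes))),
                 if (!is.null(x$mt)) list(mt = x$mt))
  purrr::imap_dfr(all_pools, function(p, nm) {
    tibble(pool = nm, offset_ppm = p$offset_ppm, fraction = p$fraction,
           exchange_rate_per_s = p$exchange_rate_per_s,
           T1_s = p$T1_s, T2_s = p$T2_s)
  })
}

#' Continuous-wave saturation parameters
#'
#' @param sat_duration_s Saturation block length, s.
#' @param recovery_s Post-readout recovery delay, s (recorded for provenance;
#'   each offset is propagated from thermal equilibrium).
#' @param B1_uT Nominal saturation amplitude, microtesla.
#' @param field_T Static field, tesla.
#' @param B1_scale Multiplicative B1 miscalibration factor.
#' @param B0_shift_ppm Additive B0 offset error, ppm.
#' @return A `sequence_params` list.
#' @export
sequence_params <- function(sat_duration_s = 5, recovery_s = 2, B1_uT = 1,
                            field_T = 4.7, B1_scale = 1, B0_shift_ppm = 0) {
  stopifnot(sat_duration_s > 0, B1_uT >= 0, B1_scale > 0,
            is.finite(B0_shift_ppm), field_T > 0)
  structure(list(sat_duration_s = sat_duration_s, recovery_s = recovery_s,
                 B1_uT = B1_uT, field_T = field_T, B1_scale = B1_scale,
                 B0_shift_ppm = B0_shift_ppm),
            class = "sequence_params")
}
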