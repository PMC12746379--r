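#' Windowed mean-substitution transform of a high-power Z-spectrum
#'
#' Tiles the offset index range into consecutive blocks of `length` indices
#' (after a truncated leading block of `shift` indices when `shift > 0`; the
#' trailing block may also be truncated). Within each block the HP block mean
#' is replaced by the LP block mean:
#' `out[i] = hp[i] - mean(hp[block]) + mean(lp[block])`.
#'
#' This moves the trajectory of the transformed spectrum onto the LP
#' Z-spectrum while every point keeps the local slope structure of the HP
#' Z-spectrum.
#'
#' @param lp,hp Numeric vectors of equal length (S/S0 values on one schedule).
#' @param length Window length in offset indices (>= 2).
#' @param shift Starting-index displacement, `0 <= shift < length`.
#' @return Numeric vector, same length as `lp`.
#' @export
transform_single_window <- function(lp, hp, length = 3L, shift = 0L) {
  if (base::length(lp) != base::length(hp)) stop("lp and hp length mismatch")
  stopifnot(length >= 2, shift >= 0, shift < length)
  n <- base::length(lp)
  if (n < length) {
    return(hp - mean(hp) + mean(lp))
  }
  starts <- if (shift > 0) c(1L, seq(shift + 1L, n, by = length)) else
    seq(1L, n, by = length)
  out <- numeric(n)
  for (s in starts) {
    idx <- s:min(s + if (s == 1L && shift > 0) shift - 1L else length - 1L, n)
    out[idx] <- hp[idx] - mean(hp[idx]) + mean(lp[idx])
  }
  out
}

#' Transformed HP Z-spectrum (dual-power feature preparation)
#'
#' Averages four single-window transforms: each window length in `lengths`
#' with shift 0 and with a half-window shift (`floor(length/2)`). The
#' averaging suppresses the zig-zag pattern a single tiling produces at block
#' edges while preserving the HP slope information.
#'
#' @inheritParams transform_single_window
#' @param lengths Integer window lengths (default 3 and 5).
#' @return Numeric vector, same length as `lp`.
#' @examples
#' lp <- c(1, 0.9, 0.8, 0.9, 1)
#' hp <- c(1, 0.7, 0.5, 0.7, 1)
#' build_transformed_hp(lp, hp)
#' @export
build_transformed_hp <- function(lp, hp, lengths = c(3, 5)) {
  transforms <- lapply(lengths, function(w) {
    list(transform_single_window(lp, hp, w, 0L),
         transform_single_window(lp, hp, w, as.integer(w %/% 2)))
  })
  Reduce(`+`, unlist(transforms, recursive = FALSE)) / (2 * base::length(lengths))
}

#' Feature angle of a Z-spectrum section
#'
#' Ordinary least-squares slope of the Z-values against the offsets inside
#' `ppm_range`, expressed in units of `normalizer` (conventionally the slope
#' of the corresponding clean LP spectrum, so that spectrum scores 1 unit).
#' The slope is reported rather than a geometric angle because the two axes
#' carry different units.
#'
#' @param values Numeric Z-values, or a `zspectrum`.
#' @param offsets_ppm Offsets in ppm (ignored when `values` is a `zspectrum`).
#' @param ppm_range Length-2 numeric `c(lo, hi)`; default 3.5–4 ppm.
#' @param normalizer Slope defining 1 unit (default 1 = raw slope).
#' @return The normalized slope (scalar).
#' @export
feature_angle <- function(values, offsets_ppm = NULL, ppm_range = c(3.5, 4),
                          normalizer = 1) {
  if (inherits(values, "zspectrum")) {
    offsets_ppm <- values$schedule$offsets_ppm
    values <- values$values
  }
  stopifnot(length(values) == length(offsets_ppm), length(ppm_range) == 2)
  sel <- offsets_ppm >= min(ppm_range) & offsets_ppm <= max(ppm_range)
  if (sum(sel) < 2) stop("fewer than 2 offsets inside ppm_range")
  x <- offsets_ppm[sel]
  y <- values[sel]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  slope / normalizer
}

#' Monte-Carlo noise robustness of the feature angle
#'
#' Adds i.i.d. Gaussian noise to a clean LP/HP spectrum pair `n_reps` times
#' and computes the feature angle of (i) the noisy LP spectrum, (ii) the
#' single-window transformed HP spectrum (length 5, no shift) and (iii) the
#' full four-window transformed HP spectrum, all in units of the clean LP
#' slope. A larger mean/std ratio means the slope estimate is more robust to
#' noise.
#'
#' @param lp_clean,hp_clean Clean `zspectrum` objects (or numeric vectors on
#'   `schedule`).
#' @param noise_level Gaussian noise standard deviation as a fraction of S0.
#' @param n_reps Number of noise replicates.
#' @param ppm_range Section used for the slope fit.
#' @param seed Integer seed.
#' @param schedule Required when `lp_clean`/`hp_clean` are bare vectors.
#' @return A `feature_angle_mc` tibble with one row per spectrum type:
#'   `spectrum`, `mean`, `std`, `ratio` (= mean/std).
#' @export
monte_carlo_feature_angle <- function(lp_clean, hp_clean, noise_level = 0.03,
                                      n_reps = 1000, ppm_range = c(3.5, 4),
                                      seed = 1L, schedule = NULL) {
  if (inherits(lp_clean, "zspectrum")) {
    schedule <- lp_clean$schedule
    lp_clean <- lp_clean$values
  }
  if (inherits(hp_clean, "zspectrum")) hp_clean <- hp_clean$values
  if (is.null(schedule)) stop("schedule required when spectra are bare vectors")
  stopifnot(n_reps >= 2, noise_level >= 0)
  offs <- schedule$offsets_ppm
  unit <- feature_angle(lp_clean, offs, ppm_range) # clean LP slope == 1 unit

  withr::local_seed(seed)
  angles <- vapply(seq_len(n_reps), function(r) {
    lp <- lp_clean + rnorm(length(lp_clean), sd = noise_level)
    hp <- hp_clean + rnorm(length(hp_clean), sd = noise_level)
    c(lp = feature_angle(lp, offs, ppm_range, unit),
      single = feature_angle(transform_single_window(lp, hp, 5L, 0L),
                             offs, ppm_range, unit),
      full = feature_angle(build_transformed_hp(lp, hp), offs, ppm_range, unit))
  }, numeric(3))

  out <- tibble(
    spectrum = c("lp", "transformed_hp_single_window", "transformed_hp"),
    mean = unname(apply(angles, 1, mean)),
    std = unname(apply(angles, 1, sd)),
  )
  out$ratio <- ifelse(out$std > 0, out$mean / out$std, Inf)
  class(out) <- c("feature_angle_mc", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.feature_angle_mc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$spectrum, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$std,
                                        ymax = .data$mean + .data$std),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "feature angle (LP units)",
                  title = "Feature-angle noise robustness")
}
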