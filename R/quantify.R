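#' Lorentzian lineshape
#'
#' `A * (G/2)^2 / ((G/2)^2 + (d - w0)^2)`: amplitude `A` (fraction of S0),
#' center `w0` and full width at half maximum `G`, all on the ppm axis.
#'
#' @param offset_ppm Offsets, ppm.
#' @param amplitude,center_ppm,fwhm_ppm Peak parameters.
#' @return Numeric vector of lineshape values.
#' @export
lorentzian <- function(offset_ppm, amplitude, center_ppm, fwhm_ppm) {
  hw2 <- (fwhm_ppm / 2)^2
  amplitude * hw2 / (hw2 + (offset_ppm - center_ppm)^2)
}

#' Default starts and bounds for the two-pool reference fit
#'
#' Configurable stand-ins for the water and semisolid MT peak parameters
#' (amplitude as fraction of S0; width and center in ppm).
#'
#' @return A list with `start`, `lower`, `upper` named vectors over
#'   `(water_A, water_w0, water_G, mt_A, mt_w0, mt_G)`.
#' @export
ld_fit_bounds <- function() {
  list(
    start = c(water_A = 0.9, water_w0 = 0, water_G = 2,
              mt_A = 0.1, mt_w0 = -2.5, mt_G = 50),
    lower = c(water_A = 0.2, water_w0 = -0.5, water_G = 0.5,
              mt_A = 0, mt_w0 = -4, mt_G = 10),
    upper = c(water_A = 1, water_w0 = 0.5, water_G = 6,
              mt_A = 0.5, mt_w0 = 0, mt_G = 100)
  )
}

#' Two-pool (water + MT) Lorentzian reference fit
#'
#' Fits `Z(d) = 1 - L_water(d) - L_mt(d)` by bounded nonlinear least squares,
#' restricted to offset ranges essentially free of CEST/NOE effects (by
#' default ±10 to ±6.25 ppm and −0.5 to 0.5 ppm). The fitted model evaluated
#' on the full schedule is the reference spectrum `S_ref` of the
#' Lorentzian-difference analysis; the fitted water center absorbs residual
#' B0 shift.
#'
#' @param values Z-spectrum values (S/S0), or a `zspectrum`.
#' @param offsets_ppm Offsets in ppm (ignored for a `zspectrum`).
#' @param fit_ranges List of `c(lo, hi)` ppm windows used in the fit.
#' @param bounds Starts/bounds as from [ld_fit_bounds()].
#' @return An `ld_fit`: `water` and `mt` peak lists (amplitude, center_ppm,
#'   fwhm_ppm), `reference` (fitted spectrum on the full schedule),
#'   `residual` (RMS residual over the fit ranges) and `converged`. On
#'   non-convergence the peaks and reference are NaN and `converged` is
#'   FALSE (no error is thrown).
#' @export
fit_reference <- function(values, offsets_ppm = NULL,
                          fit_ranges = list(c(-10, -6.25), c(-0.5, 0.5), c(6.25, 10)),
                          bounds = ld_fit_bounds()) {
  if (inherits(values, "zspectrum")) {
    offsets_ppm <- values$schedule$offsets_ppm
    values <- values$values
  }
  stopifnot(length(values) == length(offsets_ppm))
  sel <- Reduce(`|`, lapply(fit_ranges, function(r)
    offsets_ppm >= min(r) & offsets_ppm <= max(r)))
  x <- offsets_ppm[sel]
  y <- values[sel]

  model <- function(p, d) {
    1 - lorentzian(d, p[1], p[2], p[3]) - lorentzian(d, p[4], p[5], p[6])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = bounds$start,
      lower = bounds$lower, upper = bounds$upper,
      fn = function(p) y - model(p, x),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  ok <- !is.null(fit) && fit$info %in% 1:4 && all(is.finite(coef(fit)))
  if (!ok) {
    nanpeak <- list(amplitude = NaN, center_ppm = NaN, fwhm_ppm = NaN)
    return(structure(list(water = nanpeak, mt = nanpeak,
                          reference = rep(NaN, length(offsets_ppm)),
                          offsets_ppm = offsets_ppm,
                          residual = NaN, converged = FALSE),
                     class = "ld_fit"))
  }
  p <- coef(fit)
  structure(list(
    water = list(amplitude = p[["water_A"]], center_ppm = p[["water_w0"]],
                 fwhm_ppm = p[["water_G"]]),
    mt = list(amplitude = p[["mt_A"]], center_ppm = p[["mt_w0"]],
              fwhm_ppm = p[["mt_G"]]),
    reference = model(p, offsets_ppm),
    offsets_ppm = offsets_ppm,
    residual = sqrt(mean(fit$fvec^2)),
    converged = TRUE
  ), class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<ld_fit> fit did not converge\n")
  } else {
    cat(sprintf("<ld_fit> water A %.3f, w0 %.3f ppm, G %.2f ppm | MT A %.3f, w0 %.2f ppm, G %.1f ppm | rms %.2e\n",
                x$water$amplitude, x$water$center_ppm, x$water$fwhm_ppm,
                x$mt$amplitude, x$mt$center_ppm, x$mt$fwhm_ppm, x$residual))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ld_fit <- function(x, ...) {
  tibble(pool = rep(c("water", "mt"), each = 3),
         term = rep(c("amplitude", "center_ppm", "fwhm_ppm"), 2),
         estimate = c(x$water$amplitude, x$water$center_ppm, x$water$fwhm_ppm,
                      x$mt$amplitude, x$mt$center_ppm, x$mt$fwhm_ppm))
}

#' @exportS3Method generics::glance
glance.ld_fit <- function(x, ...) {
  tibble(converged = x$converged, rms_residual = x$residual)
}

#' Apparent exchange-dependent relaxation (AREX)
#'
#' `AREX(d) = (1/S_lab(d) - 1/S_ref(d)) * R1w`, in 1/s: the
#' relaxation-compensated difference between the measured label signal and
#' the fitted reference. Nonpositive signals yield NaN at that offset with a
#' warning.
#'
#' @param s_lab Measured (label) Z-values.
#' @param s_ref Reference Z-values (e.g. from [fit_reference()]).
#' @param R1w_per_s Water longitudinal relaxation rate, 1/s.
#' @return Numeric vector of AREX values, 1/s.
#' @examples
#' arex(0.5, 0.8, 1) # 0.75
#' @export
arex <- function(s_lab, s_ref, R1w_per_s) {
  stopifnot(length(s_lab) == length(s_ref))
  bad <- !(s_lab > 0 & s_ref > 0)
  if (any(bad, na.rm = TRUE))
    warning(sprintf("%d offset(s) with nonpositive signal set to NaN", sum(bad)))
  out <- (1 / s_lab - 1 / s_ref) * R1w_per_s
  out[bad] <- NaN
  out
}

#' Default per-pool peak-map windows (ppm)
#'
#' APT 3.25–3.75, PCr 2.35–2.85, guanidine 1.75–2.25, NOE(−1.6) −1.85 to
#' −1.35, NOE(−3.5) −3.75 to −3.25.
#'
#' @return Named list of `c(lo, hi)` ppm ranges.
#' @export
peak_windows <- function() {
  list(apt = c(3.25, 3.75), pcr = c(2.35, 2.85), guanidine = c(1.75, 2.25),
       noe_m1.6 = c(-1.85, -1.35), noe_m3.5 = c(-3.75, -3.25))
}

#' Per-pool peak maps from a quantified volume
#'
#' For each pool, takes the maximum spectrum value inside its ppm window,
#' voxel by voxel.
#'
#' @param volume 3-D array (x, y, offset) of LD or AREX spectra.
#' @param offsets_ppm Offsets of the third axis, ppm.
#' @param windows Named list of ppm ranges (default [peak_windows()]).
#' @return A `peak_maps` list of 2-D matrices (one per pool) with a tidy
#'   tibble available via [tidy()].
#' @export
peak_maps <- function(volume, offsets_ppm, windows = peak_windows()) {
  d <- dim(volume)
  stopifnot(length(d) == 3, d[3] == length(offsets_ppm))
  maps <- lapply(windows, function(w) {
    sel <- offsets_ppm >= min(w) & offsets_ppm <= max(w)
    if (!any(sel)) stop("peak window contains no offsets")
    apply(volume[, , sel, drop = FALSE], c(1, 2), max)
  })
  structure(maps, class = "peak_maps")
}

#' @exportS3Method generics::tidy
tidy.peak_maps <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(m, nm) {
    grid <- tidyr::expand_grid(y = seq_len(ncol(m)), x = seq_len(nrow(m)))
    tibble(pool = nm, x = grid$x, y = grid$y, value = as.numeric(m))
  })
}

#' @exportS3Method ggplot2::autoplot
autoplot.peak_maps <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~pool) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Per-pool peak maps", fill = "AREX (1/s)")
}

#' Full Lorentzian-difference analysis of one Z-spectrum
#'
#' Runs [fit_reference()], computes the raw difference spectrum
#' `S_ref - S_lab`, the AREX spectrum (Eq. form `(1/S_lab - 1/S_ref) R1w`),
#' and per-pool peak amplitudes as maxima of the AREX spectrum inside the
#' standard windows.
#'
#' @inheritParams fit_reference
#' @param R1w_per_s Water longitudinal rate for this voxel, 1/s.
#' @param windows Peak windows (default [peak_windows()]).
#' @return An `ld_result`: the `fit`, `reference`, `ld_spectrum`,
#'   `arex_spectrum` and named `peaks` vector.
#' @export
ld_analysis <- function(values, offsets_ppm = NULL, R1w_per_s = 1,
                        fit_ranges = list(c(-10, -6.25), c(-0.5, 0.5), c(6.25, 10)),
                        bounds = ld_fit_bounds(), windows = peak_windows()) {
  if (inherits(values, "zspectrum")) {
    offsets_ppm <- values$schedule$offsets_ppm
    values <- values$values
  }
  fit <- fit_reference(values, offsets_ppm, fit_ranges, bounds)
  ld <- fit$reference - values
  ax <- if (fit$converged) {
    suppressWarnings(arex(values, fit$reference, R1w_per_s))
  } else rep(NaN, length(values))
  peaks <- vapply(windows, function(w) {
    sel <- offsets_ppm >= min(w) & offsets_ppm <= max(w)
    if (!any(sel)) stop("peak window contains no offsets")
    max(ax[sel])
  }, numeric(1))
  structure(list(fit = fit, reference = fit$reference, ld_spectrum = ld,
                 arex_spectrum = ax, peaks = peaks, offsets_ppm = offsets_ppm,
                 R1w_per_s = R1w_per_s),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("<ld_result>\n")
  print(x$fit)
  cat("  peaks (1/s): ",
      paste(sprintf("%s %.4f", names(x$peaks), x$peaks), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ld_result <- function(x, ...) {
  tibble(pool = names(x$peaks), arex_peak_per_s = unname(x$peaks))
}

#' Quantify a whole image stack
#'
#' Per-voxel [ld_analysis()] over a 3-D stack: returns the AREX volume and
#' the per-pool peak maps. Voxels whose reference fit fails carry NaN.
#'
#' @param stack 3-D array (x, y, offset) of Z-values.
#' @param offsets_ppm Offsets of the third axis, ppm.
#' @param r1w_map Matrix of per-voxel R1w (1/s), or a scalar.
#' @param ... Passed to [ld_analysis()].
#' @return List with `arex` (3-D array), `maps` (a `peak_maps`), and
#'   `n_failed` voxel count.
#' @export
quantify_volume <- function(stack, offsets_ppm, r1w_map = 1, ...) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[3] == length(offsets_ppm))
  if (length(r1w_map) == 1) r1w_map <- matrix(r1w_map, d[1], d[2])
  arex_vol <- array(NaN, d)
  n_failed <- 0L
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      res <- ld_analysis(stack[i, j, ], offsets_ppm, R1w_per_s = r1w_map[i, j], ...)
      if (!res$fit$converged) n_failed <- n_failed + 1L
      arex_vol[i, j, ] <- res$arex_spectrum
    }
  }
  list(arex = arex_vol,
       maps = peak_maps(arex_vol, offsets_ppm),
       n_failed = n_failed)
}
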