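#' Mean squared / absolute error
#'
#' @param a,b Numeric vectors, matrices or arrays of identical shape.
#' @return Scalar error.
#' @export
mse <- function(a, b) {
  check_same_shape(a, b)
  mean((a - b)^2)
}

#' @rdname mse
#' @export
mae <- function(a, b) {
  check_same_shape(a, b)
  mean(abs(a - b))
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("shape mismatch")
  invisible(TRUE)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB with `peak = max(|gt|)`. Identical inputs
#' give `Inf`. Asymmetric by construction: the peak is taken from the ground
#' truth.
#'
#' @param gt Ground-truth values.
#' @param test Test values, same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(gt, test) {
  check_same_shape(gt, test)
  e <- mse(gt, test)
  if (is.na(e)) return(NaN)
  if (e == 0) return(Inf)
  10 * log10(max(abs(gt))^2 / e)
}

# 1-D Gaussian window, normalized
ssim_window <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# valid-region weighted local moments for 1-D signals / 2-D maps
ssim_filter <- function(x, w) {
  n <- length(w)
  if (is.matrix(x)) {
    nr <- nrow(x) - n + 1
    nc <- ncol(x) - n + 1
    out <- matrix(0, nr, nc)
    # separable filtering: rows then columns
    tmp <- matrix(0, nr, ncol(x))
    for (k in seq_len(n)) tmp <- tmp + w[k] * x[k:(k + nr - 1), , drop = FALSE]
    for (k in seq_len(n)) out <- out + w[k] * tmp[, k:(k + nc - 1), drop = FALSE]
    out
  } else {
    nr <- length(x) - n + 1
    out <- numeric(nr)
    for (k in seq_len(n)) out <- out + w[k] * x[k:(k + nr - 1)]
    out
  }
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard constants (`K1 = 0.01`, `K2 = 0.03`), an
#' 11-point Gaussian window (sigma 1.5; separable in 2-D) and dynamic range
#' `max(gt) - min(gt)`. Inputs smaller than the window fall back to global
#' statistics over the whole signal.
#'
#' @param gt Ground-truth 1-D spectrum or 2-D map.
#' @param test Test values, same shape.
#' @param window_size,sigma Gaussian window parameters.
#' @param K1,K2 Stability constants.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(gt, test, window_size = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  check_same_shape(gt, test)
  if (length(dim(gt) %||% 1) > 2)
    stop("ssim is defined for 1-D spectra and 2-D maps")
  L <- max(gt) - min(gt)
  if (L == 0) L <- .Machine$double.eps
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  small <- min(dim(gt) %||% length(gt)) < window_size
  if (small) {
    mu_x <- mean(gt); mu_y <- mean(test)
    var_x <- mean((gt - mu_x)^2); var_y <- mean((test - mu_y)^2)
    cov_xy <- mean((gt - mu_x) * (test - mu_y))
    return(((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
             ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2)))
  }
  w <- ssim_window(window_size, sigma)
  mu_x <- ssim_filter(gt, w)
  mu_y <- ssim_filter(test, w)
  var_x <- ssim_filter(gt * gt, w) - mu_x^2
  var_y <- ssim_filter(test * test, w) - mu_y^2
  cov_xy <- ssim_filter(gt * test, w) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(s)
}

#' Metric report for a denoised result
#'
#' @param gt Ground truth (spectrum, map, or stack flattened consistently).
#' @param test Test values, same shape.
#' @return A one-row tibble with `mse`, `mae`, `psnr_db`, `ssim`.
#' @export
metric_report <- function(gt, test) {
  tibble(mse = mse(gt, test), mae = mae(gt, test),
         psnr_db = psnr(gt, test),
         ssim = ssim(gt, test))
}
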