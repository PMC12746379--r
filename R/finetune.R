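#' PCA spectral denoising
#'
#' Column-mean-centers the voxels-by-offsets matrix, reconstructs it from the
#' top `k` principal components (by explained variance) and adds the mean
#' back. The centered reconstruction has rank at most `k`.
#'
#' @param stack Numeric matrix, voxels in rows, frequency offsets in columns.
#' @param k Number of principal components to keep.
#' @return The denoised matrix (same shape); attribute `"sdev"` carries the
#'   component standard deviations (non-increasing).
#' @export
pca_denoise <- function(stack, k = 8L) {
  stack <- as.matrix(stack)
  if (k > min(dim(stack))) stop("k exceeds the smaller matrix dimension")
  stopifnot(k >= 1, nrow(stack) >= k)
  pc <- prcomp(stack, center = TRUE, scale. = FALSE)
  kk <- seq_len(k)
  out <- pc$x[, kk, drop = FALSE] %*% t(pc$rotation[, kk, drop = FALSE])
  out <- sweep(out, 2, pc$center, `+`)
  attr(out, "sdev") <- pc$sdev
  out
}

#' Fine-tuning configuration
#'
#' Parameters of the PCA-referenced context-learning loop. The stopping
#' threshold is `threshold_factor * MSE_REF` where `MSE_REF` is the MSE
#' between the PCA-denoised and the original LP spectrum; with
#' `threshold_factor < 1` the loop cannot terminate by collapsing onto the
#' PCA reference.
#'
#' @param n_components Principal components for the PCA reference.
#' @param max_iterations Maximum number of adjustment iterations after the
#'   initial prediction.
#' @param scale_up,scale_down Multipliers applied to the difference spectrum
#'   when the prediction is too far from / too close to the PCA reference.
#' @param threshold_factor Multiplier of `MSE_REF` defining the stop threshold.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(n_components = 8L, max_iterations = 5L,
                            scale_up = 1.01, scale_down = 0.99,
                            threshold_factor = 0.8) {
  stopifnot(n_components >= 1, max_iterations >= 1,
            scale_down > 0, scale_down < 1, scale_up > 1,
            threshold_factor > 0)
  structure(list(n_components = as.integer(n_components),
                 max_iterations = as.integer(max_iterations),
                 scale_up = scale_up, scale_down = scale_down,
                 threshold_factor = threshold_factor),
            class = "finetune_config")
}

# Vectorized context-learning loop over spectra in rows. `predictor` is
# either a cest_denoiser or function(lp_matrix, hp_matrix) -> matrix.
finetune_loop <- function(predictor, lp_ori, hp_transformed, pca_ref, config) {
  predict_fun <- if (inherits(predictor, "cest_denoiser")) {
    function(lp, hp) predict(predictor, lp, hp)
  } else {
    stopifnot(is.function(predictor))
    function(lp, hp) rbind(predictor(lp, hp))
  }
  row_mse <- function(a, b) rowMeans((a - b)^2)

  mse_ref <- row_mse(pca_ref, lp_ori)
  threshold <- config$threshold_factor * mse_ref

  z <- predict_fun(lp_ori, hp_transformed)
  if (any(!is.finite(z))) stop("non-finite prediction in fine-tuning loop")
  iterations <- integer(nrow(lp_ori))
  active <- which(row_mse(pca_ref, z) >= threshold)

  it <- 0L
  while (length(active) > 0 && it < config$max_iterations) {
    it <- it + 1L
    mse_dpdl <- row_mse(pca_ref[active, , drop = FALSE], z[active, , drop = FALSE])
    scale <- ifelse(mse_dpdl > mse_ref[active], config$scale_up, config$scale_down)
    next_input <- z[active, , drop = FALSE] -
      scale * (z[active, , drop = FALSE] - lp_ori[active, , drop = FALSE])
    z_new <- predict_fun(next_input, hp_transformed[active, , drop = FALSE])
    if (any(!is.finite(z_new))) stop("non-finite prediction in fine-tuning loop")
    z[active, ] <- z_new
    iterations[active] <- it
    still <- row_mse(pca_ref[active, , drop = FALSE], z_new) >= threshold[active]
    active <- active[still]
  }
  list(z = z, iterations = iterations)
}

#' Context-learning fine-tuning of a single prediction
#'
#' Iteratively adjusts the denoiser input so the prediction approaches (but
#' does not collapse onto) a PCA-denoised reference of the original LP
#' spectrum. Each iteration computes `MSE_DPDL = MSE(pca_ref, prediction)`;
#' if it is below `threshold_factor * MSE_REF` the loop stops, otherwise the
#' difference spectrum `prediction - lp_ori` is scaled by 1.01 (prediction
#' too far from the reference, `MSE_DPDL > MSE_REF`) or 0.99 (too close),
#' subtracted from the prediction, and the result fed back as the next input.
#' At most `max_iterations` adjustment cycles run after the initial
#' prediction.
#'
#' @param model A trained `cest_denoiser`, or a `function(lp, hp)` predictor
#'   (useful for testing the update rule).
#' @param lp_ori Original (noisy) LP spectrum, numeric vector.
#' @param hp_transformed Transformed HP spectrum, numeric vector.
#' @param pca_ref PCA-denoised LP reference spectrum (from [pca_denoise()] of
#'   the whole acquisition stack).
#' @param config A [finetune_config()].
#' @return List with `z` (final denoised spectrum) and `iterations`
#'   (adjustment cycles used).
#' @export
context_finetune <- function(model, lp_ori, hp_transformed, pca_ref,
                             config = finetune_config()) {
  stopifnot(is.numeric(lp_ori), is.null(dim(lp_ori)))
  res <- finetune_loop(model, rbind(lp_ori), rbind(hp_transformed),
                       rbind(pca_ref), config)
  list(z = drop(res$z), iterations = res$iterations[1])
}

#' Denoise a full image stack
#'
#' Applies the complete per-voxel pipeline to aligned LP/HP stacks: dual-power
#' feature preparation, autoencoder prediction, and PCA-referenced
#' context-learning fine-tuning. The PCA reference is computed once from all
#' voxels of the LP stack.
#'
#' @param model A trained `cest_denoiser`.
#' @param lp_stack,hp_stack 3-D arrays (x, y, offset) of noisy Z-values.
#' @param config A [finetune_config()].
#' @param window_lengths Feature-preparation window lengths.
#' @return A `cest_denoised` list: `denoised` stack, `pca` stack (the PCA(8)
#'   reference, useful as a single-power baseline), `iterations` map, and a
#'   tidy `log` tibble of per-voxel iteration counts.
#' @export
denoise_volume <- function(model, lp_stack, hp_stack,
                           config = finetune_config(),
                           window_lengths = c(3, 5)) {
  if (!identical(dim(lp_stack), dim(hp_stack)))
    stop("lp_stack and hp_stack dimensions differ")
  d <- dim(lp_stack)
  stopifnot(length(d) == 3)
  n_vox <- d[1] * d[2]
  lp <- matrix(lp_stack, n_vox, d[3])
  hp <- matrix(hp_stack, n_vox, d[3])
  hp_t <- t(vapply(seq_len(n_vox), function(i) {
    build_transformed_hp(lp[i, ], hp[i, ], lengths = window_lengths)
  }, numeric(d[3])))
  pca_ref <- pca_denoise(lp, k = config$n_components)
  res <- finetune_loop(model, lp, hp_t, pca_ref, config)
  grid <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[1]))
  structure(list(
    denoised = array(res$z, d),
    pca = array(pca_ref, d),
    iterations = matrix(res$iterations, d[1], d[2]),
    log = tibble(x = grid$x, y = grid$y, iterations = res$iterations)
  ), class = "cest_denoised")
}

#' @export
print.cest_denoised <- function(x, ...) {
  d <- dim(x$denoised)
  cat(sprintf("<cest_denoised> %d x %d voxels x %d offsets, median %d fine-tune iteration(s)\n",
              d[1], d[2], d[3], as.integer(stats::median(x$iterations))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cest_denoised <- function(x, ...) x$log
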