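#' Denoiser architecture configuration
#'
#' The denoiser is a 1-D convolutional autoencoder mapping a two-channel
#' input (LP Z-spectrum, transformed HP Z-spectrum) of `input_len` offsets to
#' a one-channel denoised LP Z-spectrum of the same length. The encoder is
#' two conv(kernel `kernel`) + ELU + maxpool(2) blocks with `channels[1]` and
#' `channels[2]` filters; the decoder mirrors them with one transposed
#' convolution (kernel 2, stride 2) per pooling step and a final linear
#' convolution. Odd lengths are replicate-padded to the next even length
#' before pooling and cropped on the way out.
#'
#' The default kernel of 11 samples gives the bottleneck a receptive field of
#' several ppm on the dense part of the acquisition schedule — wide enough to
#' re-center the steep direct-saturation line under B0 miscalibration, which
#' short kernels cannot do.
#'
#' @param input_len Number of frequency offsets (89 for the default schedule).
#' @param in_channels Number of input channels (2: LP + transformed HP).
#' @param channels Encoder channel counts, length 2.
#' @param kernel Odd convolution kernel size.
#' @param residual Add an identity skip from the LP input channel to the
#'   output, so the decoder learns a correction rather than the full
#'   spectrum. At small training scales this preserves the amplitude of
#'   narrow CEST dips that a plain autoencoder smooths away.
#' @return A `model_config` list.
#' @export
model_config <- function(input_len = 89L, in_channels = 2L,
                         channels = c(32L, 64L), kernel = 11L,
                         residual = TRUE) {
  stopifnot(input_len >= 8, in_channels >= 1, length(channels) == 2,
            all(channels >= 1), kernel %% 2 == 1, is.logical(residual))
  # length bookkeeping through the two pad/pool stages
  l0 <- as.integer(input_len)
  l0p <- l0 + l0 %% 2L
  l1 <- l0p %/% 2L
  l1p <- l1 + l1 %% 2L
  l2 <- l1p %/% 2L
  if (l2 < 1) stop("inconsistent pooling arithmetic for this input length")
  structure(list(input_len = l0, in_channels = as.integer(in_channels),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 residual = isTRUE(residual),
                 lengths = c(l0 = l0, l0p = l0p, l1 = l1, l1p = l1p, l2 = l2,
                             residual = as.integer(isTRUE(residual)))),
            class = "model_config")
}

#' Build an untrained dual-power denoiser
#'
#' Initializes the autoencoder parameters (He-scaled Gaussian weights, zero
#' biases) deterministically from `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return A `cest_denoiser` with untrained parameters; `n_params` reports the
#'   total parameter count.
#' @export
build_denoiser <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  withr::local_seed(seed)
  K <- config$kernel
  cin <- config$in_channels
  c1 <- config$channels[1]
  c2 <- config$channels[2]
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  params <- list(
    W_conv1 = he(c1, K * cin), b_conv1 = numeric(c1),
    W_conv2 = he(c2, K * c1), b_conv2 = numeric(c2),
    W_tA1 = he(c1, c2), W_tA2 = he(c1, c2), b_tA = numeric(c1),
    W_tB1 = he(c1, c1), W_tB2 = he(c1, c1), b_tB = numeric(c1),
    W_out = he(1, K * c1), b_out = numeric(1)
  )
  structure(list(config = config, params = params, seed = seed,
                 n_params = sum(vapply(params, length, 1L)),
                 history = NULL, trained = FALSE),
            class = "cest_denoiser")
}

# full forward pass (compiled); x: (in_channels, input_len, N). Returns the
# prediction (matrix N x input_len) and, when keep_cache, the backward cache.
denoiser_forward <- function(params, cfg, x, keep_cache = FALSE) {
  nn_fwd_cpp(x, params, unname(cfg$lengths), keep_cache)
}

denoiser_backward <- function(params, cache, dpred, cfg) {
  nn_bwd_cpp(params, cache, dpred, unname(cfg$lengths))
}

# pure-R reference forward pass, kept as an independent check of the
# compiled kernels (exercised in the test suite)
denoiser_forward_ref <- function(params, cfg, x, keep_cache = FALSE) {
  L <- cfg$lengths
  pad0 <- L[["l0p"]] > L[["l0"]]
  pad1 <- L[["l1p"]] > L[["l1"]]
  h <- if (pad0) nn_pad_fwd(x) else x
  cv1 <- nn_conv_fwd(h, params$W_conv1, params$b_conv1)
  e1 <- nn_elu_fwd(cv1$y)
  p1 <- nn_pool_fwd(e1$y)
  h1 <- if (pad1) nn_pad_fwd(p1$y) else p1$y
  cv2 <- nn_conv_fwd(h1, params$W_conv2, params$b_conv2)
  e2 <- nn_elu_fwd(cv2$y)
  p2 <- nn_pool_fwd(e2$y)
  tA <- nn_tconv_fwd(p2$y, params$W_tA1, params$W_tA2, params$b_tA)
  eA <- nn_elu_fwd(tA$y)
  hA <- eA$y[, seq_len(L[["l1"]]), , drop = FALSE] # crop l1p -> l1
  tB <- nn_tconv_fwd(hA, params$W_tB1, params$W_tB2, params$b_tB)
  eB <- nn_elu_fwd(tB$y)
  out <- nn_conv_fwd(eB$y, params$W_out, params$b_out)
  pred <- out$y[, seq_len(L[["l0"]]), , drop = FALSE] # crop l0p -> l0
  pred_m <- t(matrix(pred, L[["l0"]], dim(x)[3]))
  if (isTRUE(cfg$residual)) # identity skip from the LP channel
    pred_m <- pred_m + t(matrix(x[1, seq_len(L[["l0"]]), ], L[["l0"]], dim(x)[3]))
  res <- list(pred = pred_m)
  if (keep_cache) {
    res$cache <- list(cv1 = cv1, e1 = e1, p1 = p1, cv2 = cv2, e2 = e2, p2 = p2,
                      tA = tA, eA = eA, tB = tB, eB = eB, out = out,
                      pad0 = pad0, pad1 = pad1, L = L)
  }
  res
}

# pure-R reference backward; dpred: (1, l0, N) gradient at the output.
denoiser_backward_ref <- function(params, cache, dpred) {
  L <- cache$L
  g <- list()
  d <- nn_crop_bwd(dpred, L[["l0p"]])
  bo <- nn_conv_bwd(cache$out, params$W_out, d)
  g$W_out <- bo$dW; g$b_out <- bo$db
  d <- nn_elu_bwd(cache$eB, bo$dx)
  bB <- nn_tconv_bwd(cache$tB, params$W_tB1, params$W_tB2, d)
  g$W_tB1 <- bB$dW1; g$W_tB2 <- bB$dW2; g$b_tB <- bB$db
  d <- nn_crop_bwd(bB$dx, L[["l1p"]])
  d <- nn_elu_bwd(cache$eA, d)
  bA <- nn_tconv_bwd(cache$tA, params$W_tA1, params$W_tA2, d)
  g$W_tA1 <- bA$dW1; g$W_tA2 <- bA$dW2; g$b_tA <- bA$db
  d <- nn_pool_bwd(cache$p2, bA$dx)
  d <- nn_elu_bwd(cache$e2, d)
  b2 <- nn_conv_bwd(cache$cv2, params$W_conv2, d)
  g$W_conv2 <- b2$dW; g$b_conv2 <- b2$db
  d <- if (cache$pad1) nn_pad_bwd(b2$dx) else b2$dx
  d <- nn_pool_bwd(cache$p1, d)
  d <- nn_elu_bwd(cache$e1, d)
  b1 <- nn_conv_bwd(cache$cv1, params$W_conv1, d)
  g$W_conv1 <- b1$dW; g$b_conv1 <- b1$db
  g
}

# stack LP and transformed-HP matrices (n x L) into (2, L, n)
denoiser_input <- function(lp, hp_transformed) {
  lp <- rbind(lp); hp_transformed <- rbind(hp_transformed)
  if (!identical(dim(lp), dim(hp_transformed)))
    stop("lp and hp_transformed shape mismatch")
  n <- nrow(lp); L <- ncol(lp)
  x <- array(0, c(2, L, n))
  x[1, , ] <- t(lp)
  x[2, , ] <- t(hp_transformed)
  x
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Number of epochs.
#' @param split Training fraction; the rest is validation.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for the split and shuffling.
#' @param verbose Print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100L, split = 0.8,
                         batch_size = 256L, seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 1, split > 0, split < 1,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 split = split, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train the denoiser on dual-power pairs
#'
#' Minimizes the mean squared error between the prediction and the clean LP
#' spectrum with Adam, on a random `split`/`1-split` train/validation
#' partition. The returned model carries the parameter state with the best
#' validation loss across epochs, plus the per-epoch loss curves.
#'
#' @param model A `cest_denoiser` from [build_denoiser()].
#' @param pairs A `dual_power_set` with `hp_transformed` (see
#'   [prepare_features()]) and clean LP targets.
#' @param config A [train_config()].
#' @return The trained `cest_denoiser`; `$history` is a tibble of
#'   `epoch`, `train_loss`, `val_loss`.
#' @export
train_denoiser <- function(model, pairs, config = train_config()) {
  stopifnot(inherits(model, "cest_denoiser"), inherits(pairs, "dual_power_set"),
            inherits(config, "train_config"))
  if (is.null(pairs$hp_transformed))
    stop("pairs lack hp_transformed; run prepare_features() first")
  n <- nrow(pairs$lp_noisy)
  if (n < 2) stop("need at least 2 training pairs")
  if (ncol(pairs$lp_noisy) != model$config$input_len)
    stop("pair length does not match model input_len")

  withr::local_seed(config$seed)
  idx <- sample.int(n)
  n_train <- max(1L, floor(config$split * n))
  train_idx <- idx[seq_len(n_train)]
  val_idx <- idx[-seq_len(n_train)]
  if (length(val_idx) == 0) { # tiny sets: reuse one sample for validation
    val_idx <- train_idx[1]
  }
  x_val <- denoiser_input(pairs$lp_noisy[val_idx, , drop = FALSE],
                          pairs$hp_transformed[val_idx, , drop = FALSE])
  y_val <- pairs$lp_clean[val_idx, , drop = FALSE]

  params <- model$params
  opt <- nn_adam_init(params)
  best <- list(loss = Inf, params = params)
  hist <- matrix(NA_real_, config$epochs, 2)
  L0 <- model$config$input_len

  for (ep in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    batch_losses <- c()
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      x <- denoiser_input(pairs$lp_noisy[bi, , drop = FALSE],
                          pairs$hp_transformed[bi, , drop = FALSE])
      y <- pairs$lp_clean[bi, , drop = FALSE]
      lg <- nn_loss_grad_cpp(x, y, params, unname(model$config$lengths))
      batch_losses <- c(batch_losses, lg$loss)
      step <- nn_adam_step(params, lg$grads, opt, config$learning_rate)
      params <- step$params
      opt <- step$state
    }
    val_pred <- denoiser_forward(params, model$config, x_val)$pred
    val_loss <- mean((val_pred - y_val)^2)
    hist[ep, ] <- c(mean(batch_losses), val_loss)
    if (val_loss < best$loss) best <- list(loss = val_loss, params = params)
    if (config$verbose)
      message(sprintf("epoch %3d  train %.3e  val %.3e", ep, hist[ep, 1], val_loss))
  }

  model$params <- best$params
  model$trained <- TRUE
  model$history <- tibble(epoch = seq_len(config$epochs),
                          train_loss = hist[, 1], val_loss = hist[, 2])
  model$train_config <- config
  model$n_train <- length(train_idx)
  model$n_val <- length(val_idx)
  model
}

#' Denoise Z-spectra with a trained model
#'
#' @param object A `cest_denoiser`.
#' @param lp,hp_transformed Numeric vectors (one spectrum) or matrices
#'   (spectra in rows) aligned to the model's schedule length.
#' @param ... Unused.
#' @return A vector (single input) or matrix of denoised LP spectra, order
#'   preserved.
#' @export
predict.cest_denoiser <- function(object, lp, hp_transformed, ...) {
  single <- is.null(dim(lp))
  x <- denoiser_input(lp, hp_transformed)
  if (dim(x)[2] != object$config$input_len)
    stop("input length does not match model input_len")
  pred <- denoiser_forward(object$params, object$config, x)$pred
  if (single) drop(pred) else pred
}

#' @export
print.cest_denoiser <- function(x, ...) {
  cat(sprintf("<cest_denoiser> input %d x %d, channels %d/%d, %d parameters, %s\n",
              x$config$in_channels, x$config$input_len, x$config$channels[1],
              x$config$channels[2], x$n_params,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cest_denoiser <- function(x, ...) {
  if (is.null(x$history)) return(tibble(epoch = integer(), train_loss = numeric(),
                                        val_loss = numeric()))
  x$history
}

#' @exportS3Method generics::glance
glance.cest_denoiser <- function(x, ...) {
  tibble(n_params = x$n_params, trained = x$trained,
         best_val_loss = if (is.null(x$history)) NA_real_ else min(x$history$val_loss),
         epochs = if (is.null(x$history)) 0L else nrow(x$history))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cest_denoiser <- function(object, ...) {
  stopifnot(!is.null(object$history))
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = "Denoiser training curves", y = "MSE loss")
}
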