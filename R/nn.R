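# Minimal 1-D convolutional network engine.
#
# Tensors are arrays of dim (channels, length, batch). Convolutions are
# computed as a single matrix product against an im2col matrix; gradients are
# exact and checked against finite differences in the test suite.

nn_as3d <- function(x) {
  if (length(dim(x)) == 3) x else array(x, c(dim(x), 1L))
}

# 'same' zero-padded convolution, odd kernel. W: (Cout, K*Cin), b: Cout.
nn_conv_fwd <- function(x, W, b) {
  d <- dim(x); Cin <- d[1]; L <- d[2]; N <- d[3]
  K <- ncol(W) / Cin
  p <- (K - 1) / 2
  xp <- array(0, c(Cin, L + K - 1, N))
  xp[, p + seq_len(L), ] <- x
  xcol <- matrix(0, K * Cin, L * N)
  for (k in seq_len(K)) {
    xcol[(k - 1) * Cin + seq_len(Cin), ] <- xp[, k:(k + L - 1), , drop = FALSE]
  }
  y <- W %*% xcol + b
  list(y = array(y, c(nrow(W), L, N)), xcol = xcol, dims = d, K = K)
}

nn_conv_bwd <- function(cache, W, dy) {
  d <- cache$dims; Cin <- d[1]; L <- d[2]; N <- d[3]
  K <- cache$K
  p <- (K - 1) / 2
  dym <- matrix(dy, nrow = dim(dy)[1])
  dW <- dym %*% t(cache$xcol)
  db <- rowSums(dym)
  dxcol <- t(W) %*% dym
  dxp <- array(0, c(Cin, L + K - 1, N))
  for (k in seq_len(K)) {
    dxp[, k:(k + L - 1), ] <- dxp[, k:(k + L - 1), , drop = FALSE] +
      array(dxcol[(k - 1) * Cin + seq_len(Cin), ], c(Cin, L, N))
  }
  list(dx = dxp[, p + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

# transposed convolution, kernel 2 stride 2 (exact length doubling).
# W1, W2: (Cout, Cin); output positions 2l-1 and 2l come from input position l.
nn_tconv_fwd <- function(x, W1, W2, b) {
  d <- dim(x); Cin <- d[1]; L <- d[2]; N <- d[3]
  xm <- matrix(x, Cin, L * N)
  Cout <- nrow(W1)
  y <- array(0, c(Cout, 2 * L, N))
  y[, seq(1, 2 * L, by = 2), ] <- array(W1 %*% xm + b, c(Cout, L, N))
  y[, seq(2, 2 * L, by = 2), ] <- array(W2 %*% xm + b, c(Cout, L, N))
  list(y = y, xm = xm, dims = d)
}

nn_tconv_bwd <- function(cache, W1, W2, dy) {
  d <- cache$dims; Cin <- d[1]; L <- d[2]; N <- d[3]
  dy1 <- matrix(dy[, seq(1, 2 * L, by = 2), , drop = FALSE], nrow = dim(dy)[1])
  dy2 <- matrix(dy[, seq(2, 2 * L, by = 2), , drop = FALSE], nrow = dim(dy)[1])
  list(dx = array(t(W1) %*% dy1 + t(W2) %*% dy2, d),
       dW1 = dy1 %*% t(cache$xm), dW2 = dy2 %*% t(cache$xm),
       db = rowSums(dy1) + rowSums(dy2))
}

nn_elu_fwd <- function(x) {
  neg <- x < 0
  y <- x
  y[neg] <- expm1(x[neg])
  list(y = y, neg = neg)
}

nn_elu_bwd <- function(cache, dy) {
  d <- dy
  d[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + 1) # d/dx elu = elu + 1 for x < 0
  d
}

# max pooling along length, factor 2 (length must be even)
nn_pool_fwd <- function(x) {
  d <- dim(x); L <- d[2]
  x1 <- x[, seq(1, L, by = 2), , drop = FALSE]
  x2 <- x[, seq(2, L, by = 2), , drop = FALSE]
  m <- x1 >= x2
  y <- x2
  y[m] <- x1[m]
  list(y = y, m = m, dims = d)
}

nn_pool_bwd <- function(cache, dy) {
  d <- cache$dims
  dx <- array(0, d)
  dx[, seq(1, d[2], by = 2), ] <- dy * cache$m
  dx[, seq(2, d[2], by = 2), ] <- dy * !cache$m
  dx
}

# replicate-pad one sample at the end of the length axis
nn_pad_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2] + 1, d[3]))
  y[, seq_len(d[2]), ] <- x
  y[, d[2] + 1, ] <- x[, d[2], ]
  y
}

nn_pad_bwd <- function(dy) {
  d <- dim(dy)
  dx <- dy[, seq_len(d[2] - 1), , drop = FALSE]
  dx[, d[2] - 1, ] <- dx[, d[2] - 1, , drop = FALSE] + dy[, d[2], , drop = FALSE]
  dx
}

nn_crop_bwd <- function(dy, L_full) {
  d <- dim(dy)
  dx <- array(0, c(d[1], L_full, d[3]))
  dx[, seq_len(d[2]), ] <- dy
  dx
}

# Adam optimizer step over a flat list of arrays
nn_adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

nn_adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0) # keeps vector/matrix shape
  list(t = 0, m = zeros, v = zeros)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
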