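// Compiled forward/backward kernels for the 1-D convolutional autoencoder.
//
// Tensor layout: arma::cube (channels, length, batch). Convolutions are
// im2col + one GEMM; the im2col matrices and ELU outputs are cached for the
// exact backward pass. The architecture is fixed (two conv/pool encoder
// blocks, two stride-2 transposed-conv decoder blocks, linear output conv);
// channel counts and kernel size come from the parameter shapes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// replicate-pad one sample at the end of the length axis
static cube pad1(const cube& x) {
  cube y(x.n_rows, x.n_cols + 1, x.n_slices);
  y.cols(0, x.n_cols - 1) = x;
  y.col(x.n_cols) = x.col(x.n_cols - 1);
  return y;
}

static cube pad1_bwd(const cube& dy) {
  cube dx = dy.cols(0, dy.n_cols - 2);
  dx.col(dx.n_cols - 1) += dy.col(dy.n_cols - 1);
  return dx;
}

// im2col for 'same' zero-padded convolution, odd kernel K
static mat im2col(const cube& x, uword K) {
  const uword C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const uword p = (K - 1) / 2;
  mat xc(K * C, L * N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat& xs = x.slice(n);
    for (uword k = 0; k < K; ++k) {
      // output column l draws input column l + k - p
      const sword lo = static_cast<sword>(k) - static_cast<sword>(p);
      const uword c0 = (lo < 0) ? static_cast<uword>(-lo) : 0;
      const uword c1 = (lo + static_cast<sword>(L) > static_cast<sword>(L))
                           ? L - lo - 1 : L - 1;
      xc.submat(k * C, n * L + c0, k * C + C - 1, n * L + c1) =
          xs.cols(c0 + lo, c1 + lo);
    }
  }
  return xc;
}

static cube conv_fwd(const mat& xc, const mat& W, const vec& b, uword L, uword N) {
  mat y = W * xc;
  y.each_col() += b;
  return cube(y.memptr(), W.n_rows, L, N);
}

// scatter dxcol back onto the input gradient
static cube col2im(const mat& dxc, uword C, uword L, uword N, uword K) {
  const uword p = (K - 1) / 2;
  cube dx(C, L, N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    mat& ds = dx.slice(n);
    for (uword k = 0; k < K; ++k) {
      const sword lo = static_cast<sword>(k) - static_cast<sword>(p);
      const uword c0 = (lo < 0) ? static_cast<uword>(-lo) : 0;
      const uword c1 = (lo + static_cast<sword>(L) > static_cast<sword>(L))
                           ? L - lo - 1 : L - 1;
      ds.cols(c0 + lo, c1 + lo) +=
          dxc.submat(k * C, n * L + c0, k * C + C - 1, n * L + c1);
    }
  }
  return dx;
}

static void elu_inplace(cube& x) {
  x.for_each([](double& v) { if (v < 0) v = std::expm1(v); });
}

// d/dx ELU = 1 for x >= 0, elu(x) + 1 for x < 0; needs only the output y
static cube elu_bwd(const cube& y, const cube& dy) {
  cube d = dy;
  for (uword i = 0; i < y.n_elem; ++i)
    if (y[i] < 0) d[i] = dy[i] * (y[i] + 1);
  return d;
}

static void pool_fwd(const cube& x, cube& y, ucube& m) {
  const uword C = x.n_rows, L = x.n_cols, N = x.n_slices;
  y.set_size(C, L / 2, N);
  m.set_size(C, L / 2, N);
  for (uword n = 0; n < N; ++n)
    for (uword l = 0; l < L / 2; ++l)
      for (uword c = 0; c < C; ++c) {
        const double a = x(c, 2 * l, n), b2 = x(c, 2 * l + 1, n);
        const bool first = a >= b2;
        y(c, l, n) = first ? a : b2;
        m(c, l, n) = first ? 1 : 0;
      }
}

static cube pool_bwd(const ucube& m, const cube& dy) {
  cube dx(dy.n_rows, 2 * dy.n_cols, dy.n_slices, fill::zeros);
  for (uword n = 0; n < dy.n_slices; ++n)
    for (uword l = 0; l < dy.n_cols; ++l)
      for (uword c = 0; c < dy.n_rows; ++c)
        dx(c, 2 * l + (m(c, l, n) ? 0 : 1), n) = dy(c, l, n);
  return dx;
}

// transposed conv, kernel 2 stride 2: y(:, 2l) = W1 x(:, l) + b, y(:, 2l+1) = W2 x(:, l) + b
static cube tconv_fwd(const cube& x, const mat& W1, const mat& W2, const vec& b) {
  const uword L = x.n_cols, N = x.n_slices, Cout = W1.n_rows;
  cube y(Cout, 2 * L, N);
  for (uword n = 0; n < N; ++n) {
    mat y1 = W1 * x.slice(n);
    mat y2 = W2 * x.slice(n);
    y1.each_col() += b;
    y2.each_col() += b;
    for (uword l = 0; l < L; ++l) {
      y.slice(n).col(2 * l) = y1.col(l);
      y.slice(n).col(2 * l + 1) = y2.col(l);
    }
  }
  return y;
}

static void tconv_bwd(const cube& x, const mat& W1, const mat& W2, const cube& dy,
                      cube& dx, mat& dW1, mat& dW2, vec& db) {
  const uword L = x.n_cols, N = x.n_slices;
  dx.set_size(size(x));
  dW1.zeros(W1.n_rows, W1.n_cols);
  dW2.zeros(W2.n_rows, W2.n_cols);
  db.zeros(W1.n_rows);
  for (uword n = 0; n < N; ++n) {
    mat dy1(W1.n_rows, L), dy2(W2.n_rows, L);
    for (uword l = 0; l < L; ++l) {
      dy1.col(l) = dy.slice(n).col(2 * l);
      dy2.col(l) = dy.slice(n).col(2 * l + 1);
    }
    dW1 += dy1 * x.slice(n).t();
    dW2 += dy2 * x.slice(n).t();
    db += sum(dy1, 1) + sum(dy2, 1);
    dx.slice(n) = W1.t() * dy1 + W2.t() * dy2;
  }
}

struct NNParams {
  mat W1, W2, Wo, WA1, WA2, WB1, WB2;
  vec b1, b2, bo, bA, bB;
};

static NNParams unpack_params(const List& params) {
  NNParams P;
  P.W1 = Rcpp::as<mat>(params["W_conv1"]); P.b1 = Rcpp::as<vec>(params["b_conv1"]);
  P.W2 = Rcpp::as<mat>(params["W_conv2"]); P.b2 = Rcpp::as<vec>(params["b_conv2"]);
  P.WA1 = Rcpp::as<mat>(params["W_tA1"]); P.WA2 = Rcpp::as<mat>(params["W_tA2"]);
  P.bA = Rcpp::as<vec>(params["b_tA"]);
  P.WB1 = Rcpp::as<mat>(params["W_tB1"]); P.WB2 = Rcpp::as<mat>(params["W_tB2"]);
  P.bB = Rcpp::as<vec>(params["b_tB"]);
  P.Wo = Rcpp::as<mat>(params["W_out"]); P.bo = Rcpp::as<vec>(params["b_out"]);
  return P;
}

struct NNCache {
  mat xc1, xc2, xcO;
  cube e1, e2, eA, eB, p2, hA;
  ucube m1, m2;
  uword K;
};

// forward pass; fills the cache when given one. len = (l0, l0p, l1, l1p, l2,
// residual). With residual != 0 the first input channel (the LP spectrum) is
// added to the output — an identity skip, constant w.r.t. the parameters, so
// the backward pass is unchanged.
static mat fwd_impl(const cube& x, const NNParams& P, const uvec& len, NNCache* C) {
  const uword l0 = len(0), l0p = len(1), l1 = len(2), l1p = len(3);
  const uword N = x.n_slices;
  const uword K = P.W1.n_cols / x.n_rows;

  cube x0 = (l0p > l0) ? pad1(x) : x;
  mat xc1 = im2col(x0, K);
  cube e1 = conv_fwd(xc1, P.W1, P.b1, l0p, N);
  elu_inplace(e1);
  cube p1m; ucube m1;
  pool_fwd(e1, p1m, m1);
  cube h1 = (l1p > l1) ? pad1(p1m) : p1m;
  mat xc2 = im2col(h1, K);
  cube e2 = conv_fwd(xc2, P.W2, P.b2, l1p, N);
  elu_inplace(e2);
  cube p2; ucube m2;
  pool_fwd(e2, p2, m2);
  cube eA = tconv_fwd(p2, P.WA1, P.WA2, P.bA);
  elu_inplace(eA);
  cube hA = eA.cols(0, l1 - 1);
  cube eB = tconv_fwd(hA, P.WB1, P.WB2, P.bB);
  elu_inplace(eB);
  mat xcO = im2col(eB, P.Wo.n_cols / eB.n_rows);
  cube out = conv_fwd(xcO, P.Wo, P.bo, l0p, N);

  const bool residual = len.n_elem > 5 && len(5) != 0;
  mat pred(N, l0);
  for (uword n = 0; n < N; ++n) {
    pred.row(n) = out.slice(n).cols(0, l0 - 1);
    if (residual)
      pred.row(n) += x.slice(n).submat(0, 0, 0, l0 - 1);
  }
  if (C) {
    C->xc1 = std::move(xc1); C->xc2 = std::move(xc2); C->xcO = std::move(xcO);
    C->e1 = std::move(e1); C->e2 = std::move(e2);
    C->eA = std::move(eA); C->eB = std::move(eB);
    C->p2 = std::move(p2); C->hA = std::move(hA);
    C->m1 = std::move(m1); C->m2 = std::move(m2);
    C->K = K;
  }
  return pred;
}

static List bwd_impl(const NNParams& P, const NNCache& C, const mat& dpred,
                     const uvec& len) {
  const uword l0 = len(0), l0p = len(1), l1 = len(2), l1p = len(3);
  const uword N = dpred.n_rows;
  const uword K = C.K;

  // output crop backward: zero-pad the gradient to l0p
  mat dym(1, l0p * N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword l = 0; l < l0; ++l) dym(0, n * l0p + l) = dpred(n, l);
  mat dWo = dym * C.xcO.t();
  vec dbo = sum(dym, 1);
  cube d_eB = col2im(P.Wo.t() * dym, C.eB.n_rows, l0p, N, K);
  d_eB = elu_bwd(C.eB, d_eB);

  cube d_hA; mat dWB1, dWB2; vec dbB;
  tconv_bwd(C.hA, P.WB1, P.WB2, d_eB, d_hA, dWB1, dWB2, dbB);

  cube d_eA(C.eA.n_rows, l1p, C.eA.n_slices, fill::zeros); // crop backward
  d_eA.cols(0, l1 - 1) = d_hA;
  d_eA = elu_bwd(C.eA, d_eA);

  cube d_p2; mat dWA1, dWA2; vec dbA;
  tconv_bwd(C.p2, P.WA1, P.WA2, d_eA, d_p2, dWA1, dWA2, dbA);

  cube d_e2 = pool_bwd(C.m2, d_p2);
  d_e2 = elu_bwd(C.e2, d_e2);
  mat dym2(d_e2.memptr(), d_e2.n_rows, l1p * N);
  mat dW2 = dym2 * C.xc2.t();
  vec db2 = sum(dym2, 1);
  cube d_h1 = col2im(P.W2.t() * dym2, P.W2.n_cols / K, l1p, N, K);
  cube d_p1 = (l1p > l1) ? pad1_bwd(d_h1) : d_h1;

  cube d_e1 = pool_bwd(C.m1, d_p1);
  d_e1 = elu_bwd(C.e1, d_e1);
  mat dym1(d_e1.memptr(), d_e1.n_rows, l0p * N);
  mat dW1 = dym1 * C.xc1.t();
  vec db1 = sum(dym1, 1);

  return List::create(
      Named("W_conv1") = dW1, Named("b_conv1") = db1,
      Named("W_conv2") = dW2, Named("b_conv2") = db2,
      Named("W_tA1") = dWA1, Named("W_tA2") = dWA2, Named("b_tA") = dbA,
      Named("W_tB1") = dWB1, Named("W_tB2") = dWB2, Named("b_tB") = dbB,
      Named("W_out") = dWo, Named("b_out") = dbo);
}

// [[Rcpp::export]]
List nn_fwd_cpp(const arma::cube& x, const List& params, const arma::uvec& len,
                bool keep_cache) {
  NNParams P = unpack_params(params);
  if (!keep_cache)
    return List::create(Named("pred") = fwd_impl(x, P, len, nullptr));
  NNCache C;
  mat pred = fwd_impl(x, P, len, &C);
  List cache = List::create(
      Named("xc1") = C.xc1, Named("xc2") = C.xc2, Named("xcO") = C.xcO,
      Named("e1") = C.e1, Named("e2") = C.e2, Named("eA") = C.eA,
      Named("eB") = C.eB, Named("m1") = C.m1, Named("m2") = C.m2,
      Named("p2") = C.p2, Named("hA") = C.hA, Named("K") = C.K);
  return List::create(Named("pred") = pred, Named("cache") = cache);
}

// [[Rcpp::export]]
List nn_bwd_cpp(const List& params, const List& cache, const arma::mat& dpred,
                const arma::uvec& len) {
  NNParams P = unpack_params(params);
  NNCache C;
  C.xc1 = Rcpp::as<mat>(cache["xc1"]); C.xc2 = Rcpp::as<mat>(cache["xc2"]);
  C.xcO = Rcpp::as<mat>(cache["xcO"]);
  C.e1 = Rcpp::as<cube>(cache["e1"]); C.e2 = Rcpp::as<cube>(cache["e2"]);
  C.eA = Rcpp::as<cube>(cache["eA"]); C.eB = Rcpp::as<cube>(cache["eB"]);
  C.m1 = Rcpp::as<ucube>(cache["m1"]); C.m2 = Rcpp::as<ucube>(cache["m2"]);
  C.p2 = Rcpp::as<cube>(cache["p2"]); C.hA = Rcpp::as<cube>(cache["hA"]);
  C.K = Rcpp::as<uword>(cache["K"]);
  return bwd_impl(P, C, dpred, len);
}

// fused training step: forward, MSE loss against y, exact gradients —
// nothing but the loss, prediction and gradients crosses back to R
// [[Rcpp::export]]
List nn_loss_grad_cpp(const arma::cube& x, const arma::mat& y,
                      const List& params, const arma::uvec& len) {
  NNParams P = unpack_params(params);
  NNCache C;
  mat pred = fwd_impl(x, P, len, &C);
  mat resid = pred - y;
  double loss = accu(square(resid)) / resid.n_elem;
  List grads = bwd_impl(P, C, resid * (2.0 / resid.n_elem), len);
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
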