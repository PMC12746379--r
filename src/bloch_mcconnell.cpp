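// N-pool Bloch-McConnell propagation under continuous-wave saturation.
//
// The coupled magnetization (3 components per pool) evolves under a
// time-invariant affine system dM/dt = A M + b during the saturation block,
// so the whole block is one matrix exponential of the (3N+1) augmented
// generator. All exchange is pool <-> water (star topology); detailed
// balance fixes the back rate at f * k.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// pools: one row per pool, columns
//   0: chemical shift (rad/s, relative to water)
//   1: R1 (1/s)   2: R2 (1/s)   3: proton fraction f (water row = 1)
//   4: exchange rate k pool->water (1/s; water row = 0)
// Row 0 must be water.
static mat augmented_generator(const mat& pools, double domega_rad, double w1_rad) {
  const uword n = pools.n_rows;
  mat G(3 * n + 1, 3 * n + 1, fill::zeros);

  double kw_tot = 0.0; // total water loss rate to all bound pools
  for (uword i = 1; i < n; ++i) kw_tot += pools(i, 3) * pools(i, 4);

  for (uword i = 0; i < n; ++i) {
    const uword x = 3 * i, y = 3 * i + 1, z = 3 * i + 2;
    const double theta = pools(i, 0) - domega_rad; // resonance offset from rf
    const double R1 = pools(i, 1), R2 = pools(i, 2);
    const double f = pools(i, 3), k = pools(i, 4);

    G(x, x) = -R2;  G(x, y) = theta;
    G(y, x) = -theta; G(y, y) = -R2; G(y, z) = w1_rad;
    G(z, y) = -w1_rad; G(z, z) = -R1;
    G(z, 3 * n) = R1 * f; // thermal recovery toward M0 = f

    if (i == 0) {
      // water: loses to every bound pool, gains from each
      G(x, x) -= kw_tot; G(y, y) -= kw_tot; G(z, z) -= kw_tot;
      for (uword j = 1; j < n; ++j) {
        const double kj = pools(j, 4);
        G(x, 3 * j)     += kj;
        G(y, 3 * j + 1) += kj;
        G(z, 3 * j + 2) += kj;
      }
    } else {
      const double kws = f * k; // water -> this pool
      G(x, x) -= k; G(y, y) -= k; G(z, z) -= k;
      G(x, 0) += kws; G(y, 1) += kws; G(z, 2) += kws;
    }
  }
  return G;
}

static double water_mz_after_sat(const mat& pools, double domega_rad,
                                 double w1_rad, double t_sat) {
  const uword n = pools.n_rows;
  mat G = augmented_generator(pools, domega_rad, w1_rad);
  if (!G.is_finite()) Rcpp::stop("non-finite Bloch-McConnell generator entries");
  vec m0(3 * n + 1, fill::zeros);
  for (uword i = 0; i < n; ++i) m0(3 * i + 2) = pools(i, 3); // thermal equilibrium
  m0(3 * n) = 1.0;
  vec m = expmat(G * t_sat) * m0;
  return m(2); // water Mz
}

// Z-spectrum: water Mz after saturation at each offset, normalized by the
// identical simulation at the control offset.
// [[Rcpp::export]]
arma::vec bm_zspectrum_cpp(const arma::vec& offsets_rad, const arma::mat& pools,
                           double w1_rad, double t_sat, double control_rad) {
  if (pools.n_cols != 5) Rcpp::stop("pools matrix must have 5 columns");
  if (!pools.is_finite()) Rcpp::stop("non-finite pool parameters");
  if (pools.col(3).min() < 0.0) Rcpp::stop("negative pool fraction");
  if (pools.col(4).min() < 0.0) Rcpp::stop("negative exchange rate");

  const double s0 = water_mz_after_sat(pools, control_rad, w1_rad, t_sat);
  vec z(offsets_rad.n_elem);
  for (uword i = 0; i < offsets_rad.n_elem; ++i)
    z(i) = water_mz_after_sat(pools, offsets_rad(i), w1_rad, t_sat) / s0;
  return z;
}
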