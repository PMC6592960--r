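#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// MVAR recursion x_t = sum_j A_j x_{t-j} + e_t.
// A is k x (p*k) = [A_1 ... A_p]; E is k x n (pre-drawn innovations);
// initial lags are zero. Returns k x n.
// [[Rcpp::export]]
arma::mat mvar_simulate_cpp(const arma::mat& A, const arma::mat& E, int p) {
  const int k = E.n_rows;
  const int n = E.n_cols;
  arma::mat X(k, n, arma::fill::zeros);
  for (int t = 0; t < n; ++t) {
    arma::vec x = E.col(t);
    for (int j = 1; j <= p && t - j >= 0; ++j)
      x += A.cols((j - 1) * k, j * k - 1) * X.col(t - j);
    X.col(t) = x;
  }
  return X;
}

static inline double sigm(double v, double rho1, double rho2, double s0) {
  return 1.0 / (1.0 + std::exp(-rho1 * (v - rho2))) - s0;
}

// Euler-Maruyama integration of the two-source neural-mass model.
// State layout per source: v_st,i_st, v_pe,i_pe, v_pi,i_pi, v_ie,i_ie,
// v_ii,i_ii. Innovations (scaled by noise_scale, which already includes
// kappa_e*He*C*sqrt(g_u_white*dt)) enter i_st. Output: per-source pyramidal
// depolarization v_pe - v_pi averaged within bins of `factor` fine steps.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
arma::mat nmm_simulate_cpp(const arma::vec& ke, const arma::vec& ki,
                           const arma::vec& He, const arma::vec& Hi,
                           const arma::mat& gamma, double rho1, double rho2,
                           const arma::vec& fwd_in, const arma::vec& bwd_in,
                           const arma::vec& noise_scale, const arma::vec& x0,
                           double dt, int n_out, int factor) {
  arma::vec x = x0;
  arma::vec dx(20);
  arma::mat Y(2, n_out, arma::fill::zeros);
  const double s0 = 1.0 / (1.0 + std::exp(rho1 * rho2));
  RNGScope scope;
  for (int t = 0; t < n_out; ++t) {
    for (int sub = 0; sub < factor; ++sub) {
      double P[2]  = { x(2) - x(4),  x(12) - x(14) };
      double Io[2] = { x(6) - x(8),  x(16) - x(18) };
      for (int r = 0; r < 2; ++r) {
        int o = 1 - r;
        int b = 10 * r;
        double kap[5] = { ke(r), ke(r), ki(r), ke(r), ki(r) };
        double Hm[5]  = { He(r), He(r), Hi(r), He(r), Hi(r) };
        double drv[5];
        drv[0] = gamma(r, 0) * sigm(P[r], rho1, rho2, s0) +
                 fwd_in(r) * sigm(P[o], rho1, rho2, s0);
        drv[1] = gamma(r, 1) * sigm(x(b), rho1, rho2, s0) +
                 bwd_in(r) * sigm(P[o], rho1, rho2, s0);
        drv[2] = gamma(r, 3) * sigm(Io[r], rho1, rho2, s0);
        drv[3] = gamma(r, 2) * sigm(P[r], rho1, rho2, s0) +
                 bwd_in(r) * sigm(P[o], rho1, rho2, s0);
        drv[4] = gamma(r, 4) * sigm(Io[r], rho1, rho2, s0);
        for (int m = 0; m < 5; ++m) {
          int vi = b + 2 * m;
          int ii = vi + 1;
          dx(vi) = x(ii);
          dx(ii) = kap[m] * Hm[m] * drv[m] - 2.0 * kap[m] * x(ii) -
                   kap[m] * kap[m] * x(vi);
        }
      }
      x += dt * dx;
      x(1)  += noise_scale(0) * norm_rand();
      x(11) += noise_scale(1) * norm_rand();
      if (!x.is_finite() || std::abs(x(2)) > 1e9)
        stop("neural-mass simulation diverged at t = %g s", (t * factor + sub) * dt);
      Y(0, t) += x(2) - x(4);
      Y(1, t) += x(12) - x(14);
    }
    Y.col(t) /= factor;
  }
  return Y;
}
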