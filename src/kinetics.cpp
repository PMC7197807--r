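// Compiled kernels for the linear compartment model: matrix exponential
// (Armadillo scaling-and-squaring Pade, robust to repeated eigenvalues) and
// a classical fixed-step RK4 integrator used as an independent oracle.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& A) {
  return arma::expmat(A);
}

// Propagate q through exp(A * dt) for each gap between requested times.
// times must be sorted ascending, t0 is the time q0 refers to (usually 0).
// [[Rcpp::export]]
arma::mat propagate_expm_cpp(const arma::mat& A, const arma::vec& q0,
                             const arma::vec& times, const double t0) {
  const arma::uword n = times.n_elem, m = q0.n_elem;
  arma::mat out(m, n);
  arma::vec q = q0;
  double t_prev = t0;
  for (arma::uword i = 0; i < n; ++i) {
    const double dt = times[i] - t_prev;
    if (dt > 0.0) q = arma::expmat(A * dt) * q;
    out.col(i) = q;
    t_prev = times[i];
  }
  return out;
}

// Classical 4th-order Runge-Kutta with fixed step on dq/dt = A q.
// The final partial step covers any remainder so sampling lands exactly
// on each requested time.
// [[Rcpp::export]]
arma::mat rk4_cpp(const arma::mat& A, const arma::vec& q0,
                  const arma::vec& times, const double step) {
  const arma::uword n = times.n_elem;
  arma::mat out(q0.n_elem, n);
  arma::vec q = q0;
  double t_prev = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double remaining = times[i] - t_prev;
    while (remaining > 1e-15) {
      const double h = remaining < step ? remaining : step;
      const arma::vec k1 = A * q;
      const arma::vec k2 = A * (q + 0.5 * h * k1);
      const arma::vec k3 = A * (q + 0.5 * h * k2);
      const arma::vec k4 = A * (q + h * k3);
      q += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      remaining -= h;
    }
    out.col(i) = q;
    t_prev = times[i];
  }
  return out;
}
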