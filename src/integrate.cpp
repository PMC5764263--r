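// Shared bilinear state-space integrator used by both the ground-truth
// simulator and DCM model inversion (identical numerics by construction).
//
//   dx/dt = (A + u_mod(t) * B) x + C * u_drive(t),  x(0) = 0
//
// Inputs are sampled on the integration grid; within a step they are held
// constant (boxcar inputs aligned to the grid keep RK4 at full order).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".integrate_bilinear_c")]]
arma::mat integrate_bilinear_c(const arma::mat& A, const arma::mat& B,
                               const arma::vec& C, const arma::vec& u_drive,
                               const arma::vec& u_mod, double dt,
                               int method) {
  const uword d = A.n_rows;
  const uword n = u_drive.n_elem;
  mat out(d, n, fill::zeros);
  vec x(d, fill::zeros);

  for (uword k = 0; k < n; ++k) {
    const mat M = A + u_mod(k) * B;
    const vec b = C * u_drive(k);
    if (method == 0) { // Euler
      x += dt * (M * x + b);
    } else {           // RK4 (inputs constant over the step)
      vec k1 = M * x + b;
      vec k2 = M * (x + 0.5 * dt * k1) + b;
      vec k3 = M * (x + 0.5 * dt * k2) + b;
      vec k4 = M * (x + dt * k3) + b;
      x += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    if (!x.is_finite() || norm(x, "inf") > 1e8) {
      // Unstable trajectory: clamp and fill remainder so the caller can
      // detect divergence without NaN propagation.
      out.cols(k, n - 1).fill(1e8);
      return out;
    }
    out.col(k) = x;
  }
  return out;
}
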