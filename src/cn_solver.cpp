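#include <Rcpp.h>
using namespace Rcpp;

// Crank-Nicolson propagation of the finite-volume system
//   w_j du_j/dt = off_j (u_{j+1} - u_j) - off_{j-1} (u_j - u_{j-1})
// (zero-flux boundaries), used for the allele-frequency density after a
// population-size change. Time steps follow a geometric ramp so the stiff
// early transients are resolved; the first two steps are implicit Euler
// (Rannacher smoothing) to damp high-frequency components of the initial
// condition. The tridiagonal solves use the Thomas algorithm; the system
// is diagonally dominant, so no pivoting is needed.
// [[Rcpp::export]]
NumericVector cn_propagate(NumericVector w, NumericVector off,
                           NumericVector u0, double tau,
                           int n_steps = 120, double ramp = 1e4) {
  const int K = w.size();
  std::vector<double> u(u0.begin(), u0.end());
  if (tau <= 0.0 || K < 2) return wrap(u);
  const double r = std::pow(ramp, 1.0 / (n_steps - 1));
  double dt = tau * (r - 1.0) / (std::pow(r, n_steps) - 1.0);
  std::vector<double> diag(K), rhs(K), cp(K), dp(K);
  for (int s = 0; s < n_steps; ++s) {
    const double th = (s < 2) ? 1.0 : 0.5; // implicit-Euler start, then CN
    // rhs = (w/dt) u + (1 - th) * A u ; lhs = (w/dt) I - th * A
    for (int j = 0; j < K; ++j) {
      double au = 0.0;
      if (j < K - 1) au += off[j] * (u[j + 1] - u[j]);
      if (j > 0) au -= off[j - 1] * (u[j] - u[j - 1]);
      rhs[j] = (w[j] / dt) * u[j] + (1.0 - th) * au;
      double d = w[j] / dt;
      if (j < K - 1) d += th * off[j];
      if (j > 0) d += th * off[j - 1];
      diag[j] = d;
    }
    // Thomas forward sweep: sub/super diagonals are -th * off
    cp[0] = -th * off[0] / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int j = 1; j < K; ++j) {
      const double sub = -th * off[j - 1];
      const double m = diag[j] - sub * cp[j - 1];
      cp[j] = (j < K - 1) ? (-th * off[j]) / m : 0.0;
      dp[j] = (rhs[j] - sub * dp[j - 1]) / m;
    }
    u[K - 1] = dp[K - 1];
    for (int j = K - 2; j >= 0; --j) u[j] = dp[j] - cp[j] * u[j + 1];
    dt *= r;
  }
  return wrap(u);
}
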