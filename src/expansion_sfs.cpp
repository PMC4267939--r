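#include <Rcpp.h>
using namespace Rcpp;

// Full evaluation of the post-expansion expected SFS on the Chebyshev
// finite-volume grid: cell masses and binomial sampling moments by 7-point
// Gauss-Legendre quadrature with power-law substitutions in the boundary
// cells, Crank-Nicolson propagation of the density ratio u = f/phi_new
// (geometric time-step ramp, implicit-Euler start), then integration
// against the binomial kernel. Mirrors the R reference implementation of
// the same scheme; kept in C++ because maximum-likelihood fitting calls it
// tens of thousands of times.
// [[Rcpp::export]]
NumericVector expansion_sfs_cpp(double a_new, double b_new, double c_new,
                                double a_old, double b_old, double c_old,
                                int n, int K, double tau,
                                int n_steps = 120, double ramp = 1e4) {
  static const double glx[7] = {
    0.0254460438286207, 0.1292344072003028, 0.2970774243113014, 0.5,
    0.7029225756886986, 0.8707655927996972, 0.9745539561713793};
  static const double glw[7] = {
    0.0647424830844348, 0.1398526957446383, 0.1909150252525595,
    0.2089795918367347, 0.1909150252525595, 0.1398526957446383,
    0.0647424830844348};
  const int Q = 7;
  std::vector<double> edges(K + 1);
  for (int j = 0; j <= K; ++j) edges[j] = (1.0 - std::cos(M_PI * j / K)) / 2.0;
  std::vector<double> qx(K * Q), lqx(K * Q), l1qx(K * Q);
  std::vector<double> ljn(K * Q), ljo(K * Q);
  for (int j = 0; j < K; ++j) {
    const double lo = edges[j], hi = edges[j + 1];
    for (int q = 0; q < Q; ++q) {
      const int id = j * Q + q;
      const double t = glx[q], lgw = std::log(glw[q]);
      if (j == 0) {
        // x = hi * t^(1/a) absorbs the x^(a-1) singularity
        const double x = hi * std::pow(t, 1.0 / a_new);
        qx[id] = x;
        lqx[id] = std::log(hi) + std::log(t) / a_new;
        l1qx[id] = std::log1p(-x);
        ljn[id] = lgw + a_new * std::log(hi) - std::log(a_new) +
                  (b_new - 1.0) * l1qx[id] + c_new * x;
        const double xo = hi * std::pow(t, 1.0 / a_old);
        ljo[id] = lgw + a_old * std::log(hi) - std::log(a_old) +
                  (b_old - 1.0) * std::log1p(-xo) + c_old * xo;
      } else if (j == K - 1) {
        // 1 - x = w * t^(1/b) absorbs the (1-x)^(b-1) singularity
        const double wid = 1.0 - lo;
        const double om = wid * std::pow(t, 1.0 / b_new);
        const double x = 1.0 - om;
        qx[id] = x;
        lqx[id] = std::log1p(-om);
        l1qx[id] = std::log(wid) + std::log(t) / b_new;
        ljn[id] = lgw + b_new * std::log(wid) - std::log(b_new) +
                  (a_new - 1.0) * lqx[id] + c_new * x;
        const double omo = wid * std::pow(t, 1.0 / b_old);
        ljo[id] = lgw + b_old * std::log(wid) - std::log(b_old) +
                  (a_old - 1.0) * std::log1p(-omo) + c_old * (1.0 - omo);
      } else {
        const double h = hi - lo;
        const double x = lo + h * t;
        qx[id] = x;
        lqx[id] = std::log(x);
        l1qx[id] = std::log1p(-x);
        const double lh = std::log(h);
        ljn[id] = lgw + lh + (a_new - 1.0) * lqx[id] +
                  (b_new - 1.0) * l1qx[id] + c_new * x;
        ljo[id] = lgw + lh + (a_old - 1.0) * lqx[id] +
                  (b_old - 1.0) * l1qx[id] + c_old * x;
      }
    }
  }
  double shift_n = ljn[0], shift_o = ljo[0];
  for (int id = 1; id < K * Q; ++id) {
    if (ljn[id] > shift_n) shift_n = ljn[id];
    if (ljo[id] > shift_o) shift_o = ljo[id];
  }
  std::vector<double> wq(K * Q), w(K), v(K), xbar(K);
  double wsum = 0.0, vsum = 0.0;
  for (int j = 0; j < K; ++j) {
    double wj = 0.0, vj = 0.0, xj = 0.0;
    for (int q = 0; q < Q; ++q) {
      const int id = j * Q + q;
      wq[id] = std::exp(ljn[id] - shift_n);
      wj += wq[id];
      vj += std::exp(ljo[id] - shift_o);
      xj += wq[id] * qx[id];
    }
    w[j] = wj;
    v[j] = vj;
    xbar[j] = xj / wj;
    wsum += wj;
    vsum += vj;
  }
  std::vector<double> u(K);
  for (int j = 0; j < K; ++j) u[j] = (v[j] / vsum) / (w[j] / wsum);
  // interface diffusion coefficients over cell-centroid spacings
  std::vector<double> off(K - 1);
  for (int j = 1; j < K; ++j) {
    const double e = edges[j];
    const double lD = std::log(e * (1.0 - e) / 2.0) +
                      (a_new - 1.0) * std::log(e) +
                      (b_new - 1.0) * std::log1p(-e) + c_new * e - shift_n;
    off[j - 1] = std::exp(lD) / (xbar[j] - xbar[j - 1]);
  }
  // Crank-Nicolson with geometric dt ramp, implicit-Euler first two steps
  if (tau > 0.0) {
    const double r = std::pow(ramp, 1.0 / (n_steps - 1));
    double dt = tau * (r - 1.0) / (std::pow(r, n_steps) - 1.0);
    std::vector<double> diag(K), rhs(K), cp(K), dp(K);
    for (int s = 0; s < n_steps; ++s) {
      const double th = (s < 2) ? 1.0 : 0.5;
      for (int j = 0; j < K; ++j) {
        double au = 0.0;
        if (j < K - 1) au += off[j] * (u[j + 1] - u[j]);
        if (j > 0) au -= off[j - 1] * (u[j] - u[j - 1]);
        rhs[j] = (w[j] / dt) * u[j] + (1.0 - th) * au;
        double dg = w[j] / dt;
        if (j < K - 1) dg += th * off[j];
        if (j > 0) dg += th * off[j - 1];
        diag[j] = dg;
      }
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
  }
  // integrate against the binomial sampling kernel
  NumericVector p(n + 1);
  std::vector<double> lc(n + 1);
  for (int i = 0; i <= n; ++i) {
    lc[i] = std::lgamma(n + 1.0) - std::lgamma(i + 1.0) -
            std::lgamma(n - i + 1.0);
  }
  double psum = 0.0;
  for (int i = 0; i <= n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < K; ++j) {
      double cell = 0.0;
      for (int q = 0; q < Q; ++q) {
        const int id = j * Q + q;
        cell += wq[id] * std::exp(lc[i] + i * lqx[id] + (n - i) * l1qx[id]);
      }
      acc += cell * u[j];
    }
    p[i] = acc / wsum;
    psum += p[i];
  }
  for (int i = 0; i <= n; ++i) p[i] = std::max(p[i] / psum, 0.0);
  return p;
}
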