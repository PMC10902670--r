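#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Penalised logistic regression for one lambda: IRLS outer loop with
// cyclic coordinate descent on the weighted quadratic approximation.
// X must be standardised; the intercept is unpenalised. Objective:
//   -(1/n) loglik + lambda * (mix * ||beta||_1 + (1-mix)/2 * ||beta||_2^2)
// [[Rcpp::export]]
List enet_fit_cpp(NumericMatrix X, IntegerVector y, double mix,
                  double lambda, NumericVector beta_init, double b0_init,
                  int maxit_outer, int maxit_inner, double tol) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  double b0 = b0_init;
  std::vector<double> eta(n), w(n), z(n), r(n);
  const double l1 = lambda * mix, l2 = lambda * (1.0 - mix);
  bool diverged = false;

  for (int outer = 0; outer < maxit_outer; ++outer) {
    for (int i = 0; i < n; ++i) {
      double e = b0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta[i] = e;
      double pr = 1.0 / (1.0 + std::exp(-e));
      double wi = pr * (1.0 - pr);
      if (wi < 1e-6) wi = 1e-6;
      w[i] = wi;
      z[i] = e + (y[i] - pr) / wi;
      r[i] = z[i] - e;
    }
    double sw = 0.0;
    for (int i = 0; i < n; ++i) sw += w[i];
    std::vector<double> wxx(p);
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
      wxx[j] = s / n;
    }
    double dmax_outer = 0.0;
    for (int inner = 0; inner < maxit_inner; ++inner) {
      double dmax = 0.0;
      for (int j = 0; j < p; ++j) {
        double zj = 0.0;
        for (int i = 0; i < n; ++i) zj += w[i] * X(i, j) * r[i];
        zj = zj / n + wxx[j] * beta[j];
        double bj = soft(zj, l1) / (wxx[j] + l2);
        double d = bj - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
          if (std::fabs(d) > dmax) dmax = std::fabs(d);
          beta[j] = bj;
        }
      }
      double num = 0.0;
      for (int i = 0; i < n; ++i) num += w[i] * r[i];
      double d0 = num / sw;
      b0 += d0;
      for (int i = 0; i < n; ++i) r[i] -= d0;
      if (std::fabs(d0) > dmax) dmax = std::fabs(d0);
      if (dmax > dmax_outer) dmax_outer = dmax;
      if (dmax < tol) break;
    }
    if (dmax_outer < tol) break;
    // separation guard: coefficients diverging at vanishing penalty
    double bmax = 0.0;
    for (int j = 0; j < p; ++j) bmax = std::max(bmax, std::fabs(beta[j]));
    if (bmax > 30.0) { diverged = true; break; }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = b0,
                      _["diverged"] = diverged);
}
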