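// EM for a univariate Gaussian mixture: one run from given initial means.
// Log-space E-step; component variances floored at floor_v. Returns the
// per-iteration log-likelihood trace so the ascent property can be audited.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List em_gmm1d_cpp(NumericVector x, NumericVector cnt, NumericVector mu0,
                  double tol, int max_iter, double floor_v) {
  // x: distinct observed values; cnt: their multiplicities. Weighted EM on
  // the collapsed data is exact and fast for integer-valued scores.
  const int n = x.size(), k = mu0.size();
  double N = 0.0;
  for (int i = 0; i < n; ++i) N += cnt[i];
  std::vector<double> w(k, 1.0 / k), mu(mu0.begin(), mu0.end()), v(k);
  double xbar = 0.0;
  for (int i = 0; i < n; ++i) xbar += cnt[i] * x[i];
  xbar /= N;
  double xvar = 0.0;
  for (int i = 0; i < n; ++i) xvar += cnt[i] * (x[i] - xbar) * (x[i] - xbar);
  xvar /= (N > 1 ? N - 1 : 1);
  double v0 = std::max(xvar, floor_v);
  std::fill(v.begin(), v.end(), v0);

  NumericMatrix resp(n, k);
  std::vector<double> ll_trace;
  const double log2pi = std::log(2.0 * M_PI);
  double ll = 0.0, ll_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  std::vector<double> lw(k), lv(k), lg(k);
  for (;;) {
    // E-step
    ll = 0.0;
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(w[j]);
      lv[j] = -0.5 * (log2pi + std::log(v[j]));
    }
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        lg[j] = lw[j] + lv[j] - 0.5 * d * d / v[j];
        if (lg[j] > m) m = lg[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(lg[j] - m);
      double lse = m + std::log(s);
      ll += cnt[i] * lse;
      for (int j = 0; j < k; ++j) resp(i, j) = std::exp(lg[j] - lse);
    }
    ll_trace.push_back(ll);
    if (std::abs(ll - ll_prev) < tol) { converged = true; break; }
    if (iter >= max_iter) break;
    ll_prev = ll;
    ++iter;
    // M-step
    for (int j = 0; j < k; ++j) {
      double nj = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        nj += cnt[i] * resp(i, j);
        sx += cnt[i] * resp(i, j) * x[i];
      }
      nj = std::max(nj, 1e-12);
      double muj = sx / nj;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - muj;
        sv += cnt[i] * resp(i, j) * d * d;
      }
      w[j] = nj / N;
      mu[j] = muj;
      v[j] = std::max(sv / nj, floor_v);
    }
  }
  return List::create(
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["means"] = NumericVector(mu.begin(), mu.end()),
      _["variances"] = NumericVector(v.begin(), v.end()),
      _["log_likelihood"] = ll, _["responsibilities"] = resp,
      _["n_iterations"] = iter, _["converged"] = converged,
      _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}
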