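#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One EM run for a univariate Gaussian mixture from given initial means.
// equal_var selects the pooled-variance family. Returns parameters, the
// log-likelihood trace (one entry per iteration, evaluated at the start of
// the iteration) and ok = false if a component degenerated.
// [[Rcpp::export]]
List em_gauss1d(NumericVector x, NumericVector init_means, bool equal_var,
                double tol, int max_iter, double var_floor) {
  const int n = x.size();
  const int k = init_means.size();
  std::vector<double> means(init_means.begin(), init_means.end());
  std::vector<double> weights(k, 1.0 / k);
  double x_mean = 0.0, x_var = 0.0;
  for (int i = 0; i < n; ++i) x_mean += x[i];
  x_mean /= n;
  for (int i = 0; i < n; ++i) x_var += (x[i] - x_mean) * (x[i] - x_mean);
  x_var /= (n - 1);
  std::vector<double> vars(k, std::max(x_var, var_floor));
  std::vector<double> logw(k), logsd(k), nk(k), sum1(k), sum2(k);
  std::vector<double> lp(k);
  std::vector<double> trace;
  trace.reserve(64);
  const double LOG2PI_HALF = 0.9189385332046727;  // log(2*pi)/2
  double ll = R_NegInf, ll_old = R_NegInf;
  int iter = 0;
  bool ok = true;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int j = 0; j < k; ++j) {
      logw[j] = std::log(weights[j]);
      logsd[j] = 0.5 * std::log(vars[j]);
      nk[j] = 0.0; sum1[j] = 0.0; sum2[j] = 0.0;
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double z = x[i] - means[j];
        lp[j] = logw[j] - logsd[j] - LOG2PI_HALF - 0.5 * z * z / vars[j];
        if (lp[j] > mx) mx = lp[j];
      }
      double sum = 0.0;
      for (int j = 0; j < k; ++j) sum += std::exp(lp[j] - mx);
      double lse = mx + std::log(sum);
      ll += lse;
      for (int j = 0; j < k; ++j) {
        double r = std::exp(lp[j] - lse);
        nk[j] += r;
        sum1[j] += r * x[i];
        sum2[j] += r * x[i] * x[i];
      }
    }
    trace.push_back(ll);
    for (int j = 0; j < k; ++j) {
      if (nk[j] < 1e-8) { ok = false; break; }
    }
    if (!ok) break;
    double pooled = 0.0;
    for (int j = 0; j < k; ++j) {
      weights[j] = nk[j] / n;
      double mu = sum1[j] / nk[j];
      means[j] = mu;
      double ss = sum2[j] - 2.0 * mu * sum1[j] + nk[j] * mu * mu;
      if (equal_var) pooled += ss;
      else vars[j] = std::max(ss / nk[j], var_floor);
    }
    if (equal_var) {
      double v = std::max(pooled / n, var_floor);
      for (int j = 0; j < k; ++j) vars[j] = v;
    }
    if (R_finite(ll_old) && ll - ll_old < tol && ll >= ll_old - 1e-9) break;
    ll_old = ll;
  }

  return List::create(
    _["weights"] = NumericVector(weights.begin(), weights.end()),
    _["means"] = NumericVector(means.begin(), means.end()),
    _["variances"] = NumericVector(vars.begin(), vars.end()),
    _["loglik"] = ll,
    _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
    _["iterations"] = std::min(iter, max_iter),
    _["ok"] = ok);
}
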