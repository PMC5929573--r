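#include <Rcpp.h>
using namespace Rcpp;

// Affinity propagation message passing (responsibilities/availabilities)
// on a dense similarity matrix with the preference already on the diagonal.
// Both update passes are written as column sweeps over the column-major
// matrices so the inner loops stay contiguous in memory.
// Returns the exemplar index per point (1-based), the iterations run and
// whether the exemplar set was stable for `convits` iterations.
// [[Rcpp::export]]
List ap_message_passing(NumericMatrix S, double damping, int maxit,
                        int convits) {
  const int n = S.nrow();
  std::vector<double> R(n * (size_t)n, 0.0), A(n * (size_t)n, 0.0);
  const double *s = REAL(S);
  std::vector<double> m1(n), m2(n);
  std::vector<int> argm1(n);
  std::vector<char> last_exemplar(n, 0);
  int stable = 0;
  bool converged = false;
  int iter = 0;
  const double keep = damping, upd_w = 1.0 - damping;

  for (iter = 1; iter <= maxit; ++iter) {
    // per-row largest and second-largest of A + S (column sweeps)
    std::fill(m1.begin(), m1.end(), R_NegInf);
    std::fill(m2.begin(), m2.end(), R_NegInf);
    for (int k = 0; k < n; ++k) {
      const double *ak = &A[(size_t)k * n];
      const double *sk = &s[(size_t)k * n];
      for (int i = 0; i < n; ++i) {
        double v = ak[i] + sk[i];
        if (v > m1[i]) { m2[i] = m1[i]; m1[i] = v; argm1[i] = k; }
        else if (v > m2[i]) { m2[i] = v; }
      }
    }
    // responsibilities
    for (int k = 0; k < n; ++k) {
      double *rk = &R[(size_t)k * n];
      const double *sk = &s[(size_t)k * n];
      for (int i = 0; i < n; ++i) {
        double u = sk[i] - ((argm1[i] == k) ? m2[i] : m1[i]);
        rk[i] = keep * rk[i] + upd_w * u;
      }
    }
    // availabilities
    for (int k = 0; k < n; ++k) {
      double *rk = &R[(size_t)k * n];
      double *ak = &A[(size_t)k * n];
      double total = 0.0;
      for (int i = 0; i < n; ++i) {
        if (i != k && rk[i] > 0.0) total += rk[i];
      }
      double rkk = rk[k];
      for (int i = 0; i < n; ++i) {
        double u;
        if (i == k) {
          u = total;
        } else {
          double v = rkk + total - (rk[i] > 0.0 ? rk[i] : 0.0);
          u = v < 0.0 ? v : 0.0;
        }
        ak[i] = keep * ak[i] + upd_w * u;
      }
    }
    // convergence on the exemplar indicator
    bool same = true;
    for (int k = 0; k < n; ++k) {
      char ex = (A[(size_t)k * n + k] + R[(size_t)k * n + k]) > 0 ? 1 : 0;
      if (ex != last_exemplar[k]) same = false;
      last_exemplar[k] = ex;
    }
    if (same) {
      if (++stable >= convits) { converged = true; break; }
    } else {
      stable = 0;
    }
  }

  std::vector<int> exemplars;
  for (int k = 0; k < n; ++k) {
    if (last_exemplar[k]) exemplars.push_back(k);
  }
  if (exemplars.empty()) {  // fall back to the best single candidate
    int best = 0;
    double bestv = A[0] + R[0];
    for (int k = 1; k < n; ++k) {
      double v = A[(size_t)k * n + k] + R[(size_t)k * n + k];
      if (v > bestv) { bestv = v; best = k; }
    }
    exemplars.push_back(best);
  }
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    int best = exemplars[0];
    double bestv = s[(size_t)best * n + i];
    for (size_t e = 1; e < exemplars.size(); ++e) {
      double v = s[(size_t)exemplars[e] * n + i];
      if (v > bestv) { bestv = v; best = exemplars[e]; }
    }
    labels[i] = best + 1;
  }
  for (size_t e = 0; e < exemplars.size(); ++e) {
    labels[exemplars[e]] = exemplars[e] + 1;
  }
  IntegerVector ex(exemplars.size());
  for (size_t e = 0; e < exemplars.size(); ++e) ex[e] = exemplars[e] + 1;
  return List::create(_["exemplars"] = ex, _["labels"] = labels,
                      _["iterations"] = iter, _["converged"] = converged);
}
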