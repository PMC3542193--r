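#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affinity-propagation message passing (Frey & Dueck update rules) on a
// dense similarity matrix whose diagonal holds the preferences.
//
//   r(i,k) <- s(i,k) - max_{k' != k} [ a(i,k') + s(i,k') ]
//   a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))   (i != k)
//   a(k,k) <- sum_{i' != k} max(0, r(i',k))
//
// both damped as m <- lambda * m_old + (1 - lambda) * m_new. Availabilities
// start at zero. Convergence: the candidate exemplar set
// {k : r(k,k) + a(k,k) > 0} is non-empty and unchanged for conv_window
// consecutive iterations.
// [[Rcpp::export(name = ".ap_engine")]]
List ap_engine(NumericMatrix S, double lambda, int max_iter, int conv_window) {
  const int n = S.nrow();
  const double NEG = -std::numeric_limits<double>::infinity();
  NumericMatrix R(n, n), A(n, n);
  std::vector<int> flag(n, 0);
  int stable = 0, it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    // responsibilities
    for (int i = 0; i < n; ++i) {
      double m1 = NEG, m2 = NEG;
      int a1 = -1;
      for (int k = 0; k < n; ++k) {
        double v = A(i, k) + S(i, k);
        if (v > m1) { m2 = m1; m1 = v; a1 = k; }
        else if (v > m2) { m2 = v; }
      }
      for (int k = 0; k < n; ++k) {
        double rnew = S(i, k) - (k == a1 ? m2 : m1);
        R(i, k) = lambda * R(i, k) + (1.0 - lambda) * rnew;
      }
    }
    // availabilities
    for (int k = 0; k < n; ++k) {
      double pos = 0.0;
      for (int i = 0; i < n; ++i)
        if (i != k) pos += std::max(0.0, R(i, k));
      const double rkk = R(k, k);
      for (int i = 0; i < n; ++i) {
        double anew = (i == k)
          ? pos
          : std::min(0.0, rkk + pos - std::max(0.0, R(i, k)));
        A(i, k) = lambda * A(i, k) + (1.0 - lambda) * anew;
      }
    }
    // exemplar-set stability
    bool changed = false;
    int count = 0;
    for (int k = 0; k < n; ++k) {
      int f = (R(k, k) + A(k, k) > 0.0) ? 1 : 0;
      if (f != flag[k]) changed = true;
      flag[k] = f;
      count += f;
    }
    if (!changed && count > 0) {
      if (++stable >= conv_window) { converged = true; break; }
    } else {
      stable = 0;
    }
  }

  std::vector<int> ex;
  for (int k = 0; k < n; ++k)
    if (flag[k]) ex.push_back(k + 1);
  return List::create(_["exemplars"] = wrap(ex),
                      _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
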