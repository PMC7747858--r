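#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation inner loop.
//
// The candidate change is the circular arc (i, j] (0-based cut positions,
// 0 <= i < j <= n) maximizing the two-sample t-like statistic
//   |mean(arc) - mean(complement)| / (sd * sqrt(1/k + 1/(n-k)))
// where k = j - i and sd is the sample standard deviation of the whole
// segment (invariant under permutation).  Arcs are constrained so both
// the arc and its complement hold at least min_width bins.  Ties keep the
// first arc in lexicographic (i, j) scan order.

static void max_arc(const std::vector<double>& x, int min_width,
                    int& best_i, int& best_j, double& best_stat) {
  const int n = (int)x.size();
  best_i = -1; best_j = -1; best_stat = 0.0;
  if (n < 2 * min_width) return;
  std::vector<double> S(n + 1, 0.0);
  double sum = 0.0, sumsq = 0.0;
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    sum += x[t];
    sumsq += x[t] * x[t];
  }
  const double var = (sumsq - sum * sum / n) / (n - 1);
  if (!(var > 0.0)) return;  // constant segment: no split possible
  const double sd = std::sqrt(var);
  for (int i = 0; i <= n - min_width; ++i) {
    const int jmax = std::min(n, i + n - min_width);
    for (int j = i + min_width; j <= jmax; ++j) {
      const int k = j - i;
      const double ma = (S[j] - S[i]) / k;
      const double mc = (S[n] - S[j] + S[i]) / (n - k);
      const double stat = std::fabs(ma - mc) /
        (sd * std::sqrt(1.0 / k + 1.0 / (n - k)));
      if (stat > best_stat) {
        best_stat = stat;
        best_i = i;
        best_j = j;
      }
    }
  }
}

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  int i, j; double stat;
  max_arc(v, min_width, i, j, stat);
  return List::create(_["i"] = i, _["j"] = j, _["stat"] = stat);
}

// Permutation p-value for the observed max-arc statistic, using R's RNG
// (deterministic under set.seed).  p = (count + 1) / (n_perm + 1).  The
// loop exits early once the split can no longer be accepted at `alpha`.
// [[Rcpp::export]]
double cbs_perm_pvalue(NumericVector x, int min_width, double obs,
                       int n_perm, double alpha) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  int count = 0;
  const double reject_at = alpha * (n_perm + 1);  // accept iff count + 1 < this
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int t = n - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(v[t], v[u]);
    }
    int i, j; double stat;
    max_arc(v, min_width, i, j, stat);
    if (stat >= obs - 1e-12) ++count;
    if (count + 1 >= reject_at) break;
  }
  return (count + 1.0) / (n_perm + 1.0);
}
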