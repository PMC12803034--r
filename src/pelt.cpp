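#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Penalized exact change-point search (PELT) for a change in mean of an
// i.i.d. Gaussian series with known variance: minimizes
//   sum_seg RSS(seg) + lambda * (#segments - 1)
// subject to a minimum segment length. The RSS cost is subadditive, so
// pruning with constant 0 preserves exactness.
//
// y: whitened series; lambda: penalty on the RSS scale; minseg: minimum
// segment length in samples. Returns 1-based end indices of the segments.
// [[Rcpp::export]]
IntegerVector pelt_mean_cpp(NumericVector y, double lambda, int minseg) {
  const int n = y.size();
  if (minseg < 1) minseg = 1;
  if (n < minseg) return IntegerVector::create(n);
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<double> S(n + 1), S2(n + 1);
  S[0] = 0.0; S2[0] = 0.0;
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + y[i];
    S2[i + 1] = S2[i] + y[i] * y[i];
  }

  std::vector<double> F(n + 1, inf);
  std::vector<int> prev(n + 1, 0);
  F[0] = -lambda;
  std::vector<int> cand;
  std::vector<double> vbuf;
  cand.reserve(1024);
  vbuf.reserve(1024);

  for (int t = 1; t <= n; ++t) {
    int s_new = t - minseg;  // becomes a usable segmentation end at time t
    if (s_new >= 0 && F[s_new] < inf) cand.push_back(s_new);
    const double St = S[t], S2t = S2[t];
    double best = inf;
    int bs = -1;
    const size_t m = cand.size();
    vbuf.resize(m);
    for (size_t idx = 0; idx < m; ++idx) {
      const int s = cand[idx];
      const double ds = St - S[s];
      const double v = F[s] + (S2t - S2[s]) - ds * ds / (t - s);
      vbuf[idx] = v;
      if (v < best) { best = v; bs = s; }
    }
    F[t] = (bs >= 0) ? best + lambda : inf;
    prev[t] = bs;
    if (bs >= 0) {
      // keep candidates whose unpenalized value is within lambda of best
      const double thresh = F[t];
      size_t keep = 0;
      for (size_t idx = 0; idx < m; ++idx) {
        if (vbuf[idx] <= thresh) cand[keep++] = cand[idx];
      }
      cand.resize(keep);
    }
  }

  if (!(F[n] < inf)) return IntegerVector::create(n);
  std::vector<int> ends;
  for (int t = n; t > 0; t = prev[t]) ends.push_back(t);
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
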