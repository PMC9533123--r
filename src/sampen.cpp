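#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Sample entropy match counts, Richman & Moorman convention: templates
// i = 1..N-m for both the m- and (m+1)-length counts, unordered pairs i != j
// counted once, self-matches excluded, Chebyshev distance, strict |.| < r.
// Candidate pairs are enumerated through the first embedding coordinate in
// sorted order (any Chebyshev match must agree in the first coordinate to
// within r), which prunes ~(1 - P(|d| < r)) of all pairs before the inner
// coordinate check. Returns c(A, B) = ((m+1)-matches, m-matches).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector y, int m, double r) {
  const int n = y.size();
  const int N = n - m;          // number of templates
  const double *x = REAL(y);
  std::vector<int> idx(N);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  long long A = 0, B = 0;
  for (int a = 0; a < N - 1; ++a) {
    const int i = idx[a];
    const double xi = x[i];
    for (int b = a + 1; b < N; ++b) {
      const int j = idx[b];
      if (x[j] - xi >= r) break;          // sorted: no later b can match
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) >= r) { match = false; break; }
      }
      if (match) {
        ++B;
        if (std::abs(x[i + m] - x[j + m]) < r) ++A;
      }
    }
  }
  return NumericVector::create((double)A, (double)B);
}

// Coarse-grain x at each scale (non-overlapping window means), normalize per
// the tolerance mode, and return the sample entropy per scale: one call per
// (channel, epoch) instead of one per scale. r_ref is the absolute tolerance
// used when per_scale is false (global mode). NA marks undefined entries.
// [[Rcpp::export]]
NumericVector mse_scales_cpp(NumericVector x, IntegerVector scales, int m,
                             double r, bool per_scale, double r_ref) {
  const int n = x.size();
  NumericVector out(scales.size(), NA_REAL);
  std::vector<double> y;
  for (int si = 0; si < scales.size(); ++si) {
    const int tau = scales[si];
    const int nc = n / tau;
    if (nc < m + 2) continue;
    y.assign(nc, 0.0);
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int k = j * tau; k < (j + 1) * tau; ++k) s += x[k];
      y[j] = s / tau;
    }
    double rr = r_ref;
    if (per_scale) {
      double mu = 0.0, ss = 0.0;
      for (double v : y) mu += v;
      mu /= nc;
      for (double &v : y) { v -= mu; ss += v * v; }
      double sd = std::sqrt(ss / nc);
      if (sd <= 0.0) continue;
      for (double &v : y) v /= sd;
      rr = r;
    }
    NumericVector yy(y.begin(), y.end());
    NumericVector ab = sampen_counts_cpp(yy, m, rr);
    if (ab[0] > 0 && ab[1] > 0) out[si] = -std::log(ab[0] / ab[1]);
  }
  return out;
}
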