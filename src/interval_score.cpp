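#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Maximum interval score |sum(x[i..j])| / sqrt(j - i + 1) over all intervals,
// by exhaustive O(n^2) scan. Ties broken by leftmost start, then shortest
// interval (guaranteed by scan order with strict improvement).
// Returns 1-based [from, to] and the score divided by sigma.
// [[Rcpp::export(name = ".max_interval_exact")]]
List max_interval_exact(NumericVector x, double sigma) {
  int n = x.size();
  std::vector<double> ps(n + 1, 0.0);
  for (int i = 0; i < n; ++i) ps[i + 1] = ps[i] + x[i];
  double best = -1.0;
  int bi = 0, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = std::fabs(ps[j + 1] - ps[i]) / std::sqrt((double)(j - i + 1));
      if (s > best) { best = s; bi = i; bj = j; }
    }
  }
  return List::create(_["from"] = bi + 1, _["to"] = bj + 1,
                      _["score"] = (bj >= 0 ? best / sigma : 0.0));
}

// Multi-resolution approximate maximizer: scans a dense short-length family
// plus a geometric grid of longer lengths, then refines by an exact search
// in a window around the best candidate's boundaries.
// [[Rcpp::export(name = ".max_interval_fast")]]
List max_interval_fast(NumericVector x, double sigma) {
  int n = x.size();
  std::vector<double> ps(n + 1, 0.0);
  for (int i = 0; i < n; ++i) ps[i + 1] = ps[i] + x[i];

  std::vector<int> lengths;
  for (int L = 1; L <= std::min(n, 32); ++L) lengths.push_back(L);
  double L = 32.0;
  while ((int)L < n) {
    L *= 1.1;
    int Li = std::min((int)L, n);
    if (lengths.empty() || Li > lengths.back()) lengths.push_back(Li);
  }
  if (lengths.back() != n) lengths.push_back(n);

  double best = -1.0;
  int bi = 0, bj = -1;
  for (size_t k = 0; k < lengths.size(); ++k) {
    int Lk = lengths[k];
    double inv = 1.0 / std::sqrt((double)Lk);
    for (int i = 0; i + Lk <= n; ++i) {
      double s = std::fabs(ps[i + Lk] - ps[i]) * inv;
      if (s > best) { best = s; bi = i; bj = i + Lk - 1; }
    }
  }
  if (bj < 0)
    return List::create(_["from"] = 1, _["to"] = 0, _["score"] = 0.0);

  // window wide enough to bridge the geometric length gaps (ratio 1.1)
  int w = std::max(6, (int)std::ceil(0.25 * (bj - bi + 1)) + 4);
  int lo_i = std::max(0, bi - w), hi_i = std::min(n - 1, bi + w);
  int lo_j = std::max(0, bj - w), hi_j = std::min(n - 1, bj + w);
  for (int i = lo_i; i <= hi_i; ++i) {
    for (int j = std::max(i, lo_j); j <= hi_j; ++j) {
      double s = std::fabs(ps[j + 1] - ps[i]) / std::sqrt((double)(j - i + 1));
      if (s > best) { best = s; bi = i; bj = j; }
    }
  }
  return List::create(_["from"] = bi + 1, _["to"] = bj + 1,
                      _["score"] = best / sigma);
}
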