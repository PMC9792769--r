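#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Two-sided KS enrichment component for a sorted 1-based rank vector pos
// within a universe of size n: a = max_j(j/t - pos_j/n),
// b = max_j(pos_j/n - (j-1)/t); returns a if a > b else -b.
static double ks_from_sorted(const std::vector<int>& pos, int n) {
  const int t = static_cast<int>(pos.size());
  double a = R_NegInf, b = R_NegInf;
  for (int j = 1; j <= t; ++j) {
    const double pj = static_cast<double>(pos[j - 1]) / n;
    const double aj = static_cast<double>(j) / t - pj;
    const double bj = pj - static_cast<double>(j - 1) / t;
    if (aj > a) a = aj;
    if (bj > b) b = bj;
  }
  return (a > b) ? a : -b;
}

static inline int sgn(double x) { return (x > 0) - (x < 0); }

// Null connectivity raw scores: each permutation draws disjoint random up-
// and down-gene sets of the observed sizes from a universe of n genes
// (partial Fisher-Yates driven by R's RNG, so results are reproducible
// under set.seed), computes both KS components and applies the same-sign
// zeroing rule raw = 0 if sign(ks_up) == sign(ks_down) else ks_up - ks_down.
// [[Rcpp::export(name = ".ksNullRaw")]]
NumericVector ksNullRaw(int tUp, int tDown, int n, int nPerm) {
  if (tUp < 1 || tDown < 1 || tUp + tDown > n) {
    stop("invalid set sizes for permutation null");
  }
  NumericVector out(nPerm);
  std::vector<int> idx(n);
  std::vector<int> up(tUp), down(tDown);
  const int k = tUp + tDown;
  for (int i = 0; i < n; ++i) idx[i] = i + 1;
  for (int b = 0; b < nPerm; ++b) {
    for (int i = 0; i < k; ++i) {
      int j = i + static_cast<int>(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    up.assign(idx.begin(), idx.begin() + tUp);
    down.assign(idx.begin() + tUp, idx.begin() + k);
    std::sort(up.begin(), up.end());
    std::sort(down.begin(), down.end());
    const double ku = ks_from_sorted(up, n);
    const double kd = ks_from_sorted(down, n);
    out[b] = (sgn(ku) == sgn(kd)) ? 0.0 : ku - kd;
  }
  return out;
}
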