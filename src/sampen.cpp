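#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-match counts for sample entropy, Richman-Moorman convention:
// templates i = 1..N-m for both lengths m and m+1 (equal template counts),
// Chebyshev distance, ties at exactly r count as matches, self-matches
// excluded. Candidate pairs are pruned by sorting on the first template
// coordinate (a pair can only match if its first coordinates are within r),
// which leaves the counts exact while skipping most of the N^2 pairs.
// Returns the raw ordered-pair counts (each unordered pair twice).
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;            // templates of both lengths, i = 1..N-m
  if (nt < 2) stop("sequence too short for m = %d", m);
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;         // unordered pair counts, doubled below
  int hi = 0;
  for (int p = 0; p < nt; ++p) {
    const int i = ord[p];
    const double xi0 = x[i];
    if (hi < p + 1) hi = p + 1;
    while (hi < nt && x[ord[hi]] - xi0 <= r) ++hi;
    for (int q = p + 1; q < hi; ++q) {
      const int j = ord[q];
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["matches_m"] = 2.0 * B, _["matches_m1"] = 2.0 * A,
                      _["n_templates"] = (double)nt);
}
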