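#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// unit-cost insertions, deletions, substitutions and adjacent transpositions,
// with no substring edited twice.
static int osa_dist(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, prev2[j - 2] + 1);
      cur[j] = v;
    }
    prev2.swap(prev);
    prev.swap(cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector cpp_osa(std::string q, CharacterVector names) {
  const int n = names.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = osa_dist(q, std::string(names[i]));
  }
  return out;
}

// Smith-Waterman local alignment with linear gap penalties.
// Ties for the maximum cell resolve to the smallest (end-row, end-col);
// traceback prefers diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("smith_waterman: empty string");
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  const int W = m + 1;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = H[(size_t)(i - 1) * W + (j - 1)] + s;
      v = std::max(v, H[(size_t)(i - 1) * W + j] + gap);
      v = std::max(v, H[(size_t)i * W + (j - 1)] + gap);
      v = std::max(v, 0);
      H[(size_t)i * W + j] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, pairs = 0;
  while (i > 0 && j > 0 && H[(size_t)i * W + j] > 0) {
    const int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
    const int h = H[(size_t)i * W + j];
    if (h == H[(size_t)(i - 1) * W + (j - 1)] + s) { ++pairs; --i; --j; }
    else if (h == H[(size_t)(i - 1) * W + j] + gap) { --i; }
    else { --j; }
  }
  int a_start = i, a_end = bi, b_start = j, b_end = bj;
  if (best == 0) { a_start = a_end = b_start = b_end = 0; pairs = 0; }
  return List::create(
    _["score"] = best,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["aligned_pairs"] = pairs);
}
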