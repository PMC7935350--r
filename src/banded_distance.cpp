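#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <string>

using namespace Rcpp;

// Unit-cost Levenshtein distance between a and b, computed in a band of
// width 2k+1 around the main diagonal. Returns -1 when the distance
// exceeds k. Any symbol pair that is not an exact ACGT match counts as a
// mismatch (IUPAC ambiguity codes are never treated as wildcards).
static int banded_lev(const std::string &a, const std::string &b, int k) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (std::abs(n - m) > k) return -1;
  const int INF = INT_MAX / 4;
  const int w = 2 * k + 1;
  // prev[j - (i - k)] holds D(i, j) for j in [i-k, i+k]
  std::vector<int> prev(w, INF), cur(w, INF);
  for (int j = 0; j <= std::min(k, m); ++j) prev[j + k] = j; // row i = 0
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - k), hi = std::min(m, i + k);
    std::fill(cur.begin(), cur.end(), INF);
    int rowmin = INF;
    for (int j = lo; j <= hi; ++j) {
      int off = j - (i - k);
      int best = INF;
      if (j == 0) {
        best = i;
      } else {
        int diag = (j - 1 >= (i - 1) - k && j - 1 <= (i - 1) + k)
                       ? prev[(j - 1) - (i - 1) + k]
                       : INF;
        int up = (j >= (i - 1) - k && j <= (i - 1) + k) ? prev[j - (i - 1) + k]
                                                        : INF;
        int left = (off - 1 >= 0) ? cur[off - 1] : INF;
        int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
        best = std::min(std::min(diag == INF ? INF : diag + cost,
                                 up == INF ? INF : up + 1),
                        left == INF ? INF : left + 1);
      }
      cur[off] = best;
      rowmin = std::min(rowmin, best);
    }
    if (rowmin > k) return -1;
    prev.swap(cur);
  }
  int d = (m >= n - k && m <= n + k) ? prev[m - n + k] : INF;
  return (d <= k) ? d : -1;
}

// Full-matrix edit distance with free leading/trailing gaps in either
// sequence (overlap alignment). Research mode for partially overlapping
// contigs; not banded.
static int end_free_dist(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = std::min(n, m) == 0 ? 0 : INT_MAX / 4;
  if (n == 0 || m == 0) return 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0; // free leading gap in b
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      cur[j] = std::min(std::min(prev[j - 1] + cost, prev[j] + 1),
                        cur[j - 1] + 1);
    }
    if (i == n) {
      for (int j = 0; j <= m; ++j) best = std::min(best, cur[j]);
    }
    best = std::min(best, cur[m]); // free trailing gap in b
    prev.swap(cur);
  }
  return best;
}

// [[Rcpp::export(name = ".banded_edit_distance_cpp")]]
IntegerVector banded_edit_distance_cpp(CharacterVector a, CharacterVector b,
                                       int k, bool end_free) {
  const R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("`a` and `b` must have equal length or length 1");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    int d;
    if (end_free) {
      d = end_free_dist(sa, sb);
      if (d > k) d = -1;
    } else {
      d = banded_lev(sa, sb, k);
    }
    out[i] = (d < 0) ? NA_INTEGER : d;
  }
  return out;
}
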