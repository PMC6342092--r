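#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Banded Levenshtein distance with early exit: returns the exact unit-cost
// edit distance when it is <= max_dist, and max_dist + 1 otherwise.
// Cells outside the diagonal band of half-width max_dist cannot lie on an
// alignment path of cost <= max_dist, so only the band is evaluated.
static int bounded_levenshtein(const std::string &a, const std::string &b,
                               int max_dist) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (std::abs(la - lb) > max_dist) return max_dist + 1;
  const int INF = max_dist + 1;
  std::vector<int> prev(lb + 1, INF), cur(lb + 1, INF);
  for (int j = 0; j <= std::min(lb, max_dist); ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    const int jlo = std::max(1, i - max_dist);
    const int jhi = std::min(lb, i + max_dist);
    std::fill(cur.begin(), cur.end(), INF);
    if (i <= max_dist) cur[0] = i;
    int row_min = cur[0];
    for (int j = jlo; j <= jhi; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      cur[j] = std::min(d, INF);
      if (cur[j] < row_min) row_min = cur[j];
    }
    if (row_min > max_dist) return max_dist + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], INF);
}

// [[Rcpp::export(name = ".bounded_edit_distance")]]
IntegerVector bounded_edit_distance(std::string query,
                                    std::vector<std::string> subjects,
                                    int max_dist) {
  IntegerVector out(subjects.size());
  for (size_t i = 0; i < subjects.size(); ++i) {
    out[i] = bounded_levenshtein(query, subjects[i], max_dist);
  }
  return out;
}
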