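#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Unit-cost global alignment statistics: the Levenshtein distance d and,
// among all minimum-edit alignments, the maximum number of match columns M.
// The pair (d, M) is symmetric in the two sequences (reversing an alignment
// swaps insertions and deletions, keeping edits and matches), which makes
// identity M / (M + d) well-defined across co-optimal alignments.
// Lexicographic DP (min edits, then max matches) over two rolling rows.

// [[Rcpp::export]]
IntegerVector edit_alignment_stats(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> dprev(m + 1), dcur(m + 1), mprev(m + 1), mcur(m + 1);
  for (int j = 0; j <= m; ++j) { dprev[j] = j; mprev[j] = 0; }
  for (int i = 1; i <= n; ++i) {
    dcur[0] = i; mcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      int dd = dprev[j - 1] + (eq ? 0 : 1);
      int mm = mprev[j - 1] + (eq ? 1 : 0);
      const int ddel = dprev[j] + 1;
      if (ddel < dd || (ddel == dd && mprev[j] > mm)) {
        dd = ddel; mm = mprev[j];
      }
      const int dins = dcur[j - 1] + 1;
      if (dins < dd || (dins == dd && mcur[j - 1] > mm)) {
        dd = dins; mm = mcur[j - 1];
      }
      dcur[j] = dd; mcur[j] = mm;
    }
    std::swap(dprev, dcur);
    std::swap(mprev, mcur);
  }
  return IntegerVector::create(dprev[m], mprev[m]);
}
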