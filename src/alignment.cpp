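#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment statistics under the scoring scheme
// match = 1, mismatch = 0, gap = 0.  With this scheme the optimal score is
// the maximum number of identically aligned residue pairs over all global
// alignments (equivalently, the length of the longest common subsequence).
// A secondary objective -- the number of residue-residue (paired) columns,
// maximised among score-optimal alignments -- is reported for coverage
// calculations.
//
// Returns an integer matrix with one row per input pair and columns
// (matches, paired).

// [[Rcpp::export(name = ".align_pair_stats")]]
IntegerMatrix align_pair_stats(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n)
    stop("'a' and 'b' must have the same length");
  IntegerMatrix out(n, 2);

  for (R_xlen_t k = 0; k < n; ++k) {
    if (a[k] == NA_STRING || b[k] == NA_STRING)
      stop("NA sequence at position %d", (int)(k + 1));
    std::string sa = as<std::string>(a[k]);
    std::string sb = as<std::string>(b[k]);
    size_t la = sa.size(), lb = sb.size();
    if (la == 0 || lb == 0)
      stop("empty sequence at position %d", (int)(k + 1));

    // dp rows: (matches, paired) with lexicographic maximisation
    std::vector<int> pm(lb + 1, 0), pp(lb + 1, 0);  // previous row
    std::vector<int> cm(lb + 1, 0), cp(lb + 1, 0);  // current row

    for (size_t i = 1; i <= la; ++i) {
      cm[0] = 0; cp[0] = 0;
      for (size_t j = 1; j <= lb; ++j) {
        int dm = pm[j - 1] + (sa[i - 1] == sb[j - 1] ? 1 : 0);
        int dp_ = pp[j - 1] + 1;
        int bm = dm, bp = dp_;
        // gap in b (consume a_i)
        if (pm[j] > bm || (pm[j] == bm && pp[j] > bp)) { bm = pm[j]; bp = pp[j]; }
        // gap in a (consume b_j)
        if (cm[j - 1] > bm || (cm[j - 1] == bm && cp[j - 1] > bp)) {
          bm = cm[j - 1]; bp = cp[j - 1];
        }
        cm[j] = bm; cp[j] = bp;
      }
      std::swap(pm, cm);
      std::swap(pp, cp);
    }
    out(k, 0) = pm[lb];
    out(k, 1) = pp[lb];
  }
  colnames(out) = CharacterVector::create("matches", "paired");
  return out;
}
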