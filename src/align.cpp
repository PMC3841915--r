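#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs:
// match +1, mismatch -1, gap -2 per gap column. Identity is
// matches / alignment length (gap columns included). Traceback prefers
// diagonal moves over gaps on equal score, then a gap in `b` over a gap
// in `a`, so results are deterministic.
static void nw_align(const std::string &a, const std::string &b,
                     int &score, int &matches, int &aln_len) {
  const int n = (int)a.size(), m = (int)b.size();
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  std::vector<int> prev(m + 1), cur(m + 1);
  // full DP matrix of traceback moves: 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = GAP * j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = GAP * i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      int up = prev[j] + GAP;
      int left = cur[j - 1] + GAP;
      int best = sub; unsigned char mv = 0;
      if (up > best) { best = up; mv = 1; }
      if (left > best) { best = left; mv = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  score = prev[m];
  // traceback
  matches = 0; aln_len = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char mv = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && mv == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (mv == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++aln_len;
  }
}

// [[Rcpp::export]]
List nw_identity_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  int score, matches, aln_len;
  nw_align(a, b, score, matches, aln_len);
  return List::create(_["score"] = score,
                      _["matches"] = matches,
                      _["length"] = aln_len,
                      _["identity"] = (double)matches / (double)aln_len);
}

// Condensed pairwise distance vector d = 1 - identity over all pairs
// (i < j), ordered as R's dist(): (1,2), (1,3), ..., (1,n), (2,3), ...
// Each pair is aligned in canonical (lexicographic) order so that the
// identity is symmetric under the traceback tie rule.
// [[Rcpp::export]]
NumericVector nw_distances_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericVector d((R_xlen_t)n * (n - 1) / 2);
  R_xlen_t idx = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s[i] == s[j]) { d[idx++] = 0.0; continue; }
      const std::string &x = (s[i] <= s[j]) ? s[i] : s[j];
      const std::string &y = (s[i] <= s[j]) ? s[j] : s[i];
      int score, matches, aln_len;
      nw_align(x, y, score, matches, aln_len);
      d[idx++] = 1.0 - (double)matches / (double)aln_len;
    }
    Rcpp::checkUserInterrupt();
  }
  return d;
}
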