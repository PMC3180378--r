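// Weighted base-pair maximisation (Nussinov-style) secondary-structure
// folding with traceback.  Pair scores: GC 3, AU 2, GU 1; minimum hairpin
// loop of 3 unpaired bases.  The reported "mfe" is the negated total pair
// weight, so more stable structures are more negative.  Tie-breaking is
// deterministic: at (i,j) the traceback leaves j unpaired when that is
// optimal, and otherwise pairs j with the smallest admissible k.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G') ||
      (a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

static const int MINLOOP = 3;

// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(std::string seq) {
  int n = (int) seq.size();
  for (int i = 0; i < n; ++i) seq[i] = (char) toupper(seq[i]);
  // W[i][j]: best score on [i, j], 0-based inclusive
  std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
  for (int d = MINLOOP + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int best = W[i][j - 1];                    // j unpaired
      for (int k = i; k <= j - MINLOOP - 1; ++k) {
        int s = pair_score(seq[k], seq[j]);
        if (s == 0) continue;
        int left = (k > i) ? W[i][k - 1] : 0;
        int inner = (k + 1 <= j - 1) ? W[k + 1][j - 1] : 0;
        int cand = left + inner + s;
        if (cand > best) best = cand;
      }
      W[i][j] = best;
    }
  }

  // traceback
  std::vector<int> partner(n, -1);
  std::vector<std::pair<int,int> > stackiv;
  if (n > 0) stackiv.push_back(std::make_pair(0, n - 1));
  while (!stackiv.empty()) {
    int i = stackiv.back().first, j = stackiv.back().second;
    stackiv.pop_back();
    if (j - i <= MINLOOP) continue;
    if (W[i][j] == W[i][j - 1]) {                // prefer j unpaired on ties
      stackiv.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - MINLOOP - 1; ++k) { // then smallest outer index
      int s = pair_score(seq[k], seq[j]);
      if (s == 0) continue;
      int left = (k > i) ? W[i][k - 1] : 0;
      int inner = (k + 1 <= j - 1) ? W[k + 1][j - 1] : 0;
      if (left + inner + s == W[i][j]) {
        partner[k] = j; partner[j] = k;
        if (k > i) stackiv.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stackiv.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  std::string db(n, '.');
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) { db[i] = '('; db[partner[i]] = ')'; ++npairs; }
  }
  IntegerMatrix pairs(npairs, 2);
  int w = 0, total = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      pairs(w, 0) = i + 1;            // 1-based for R
      pairs(w, 1) = partner[i] + 1;
      total += pair_score(seq[i], seq[partner[i]]);
      ++w;
    }
  }
  return List::create(_["structure"] = db,
                      _["score"] = total,
                      _["pairs"] = pairs);
}

// Leftmost position (1-based; 0 if none) at which a prefix of `adaptor`
// of length >= min_overlap matches the read suffix starting there, with
// at most floor(overlap / 10) * allow_per10 mismatches.
// [[Rcpp::export(name = ".adaptor_positions")]]
IntegerVector adaptor_positions(CharacterVector reads, std::string adaptor,
                                int min_overlap, int allow_per10) {
  int n = reads.size();
  int alen = (int) adaptor.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = (int) LENGTH(STRING_ELT(reads, r));
    int found = 0;
    for (int p = 0; p + min_overlap <= len; ++p) {
      int L = len - p; if (L > alen) L = alen;
      int allowed = (L / 10) * allow_per10;
      int mm = 0;
      bool ok = true;
      for (int q = 0; q < L; ++q) {
        if (s[p + q] != adaptor[q]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) { found = p + 1; break; }
    }
    out[r] = found;
  }
  return out;
}
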