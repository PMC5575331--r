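#include <Rcpp.h>
#include <vector>
#include <string>

// Nussinov-style base-pair maximization with a minimum hairpin loop of
// `min_loop` unpaired nucleotides.  Allowed pairs: Watson-Crick plus G:U.
// Traceback is deterministic: leaving the 3'-most base unpaired is preferred
// when it costs nothing, and otherwise the 5'-most pairing partner is taken,
// so equal-score structures resolve toward 5'-most pairs.

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'U';
  case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'U';
  case 'C': return b == 'G';
  default:  return false;
  }
}

// [[Rcpp::export(name = ".fold_nussinov_cpp")]]
std::string fold_nussinov_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n < 1) return std::string();
  // DNA -> RNA, uppercase
  for (int i = 0; i < n; ++i) {
    char c = std::toupper(seq[i]);
    if (c == 'T') c = 'U';
    seq[i] = c;
  }
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = (k > i ? M[i][k - 1] : 0) + 1 + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  // iterative traceback over subproblem stack
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    if (M[i][j] == M[i][j - 1]) {  // prefer j unpaired on ties
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {  // 5'-most partner
      if (!can_pair(seq[k], seq[j])) continue;
      int v = (k > i ? M[i][k - 1] : 0) + 1 + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return db;
}
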