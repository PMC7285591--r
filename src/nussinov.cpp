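#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base-pair maximization by dynamic programming with a minimum hairpin
// size, plus traceback to a nested dot-bracket. Pairing rules: A-U (T
// treated as U), G-C, and the G-U wobble.

static inline bool canPair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export(name = ".nussinovCpp", rng = false)]]
List nussinovCpp(std::string seq, int minLoop = 3) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'U')
      stop("invalid character in sequence: %c", c);
  }
  std::string db(n, '.');
  if (n == 0) return List::create(_["dotbracket"] = db, _["pairs"] = 0);

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = minLoop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + 1; k <= j; ++k) {
        if (k - i > minLoop && canPair(seq[i], seq[k])) {
          int left = (k > i + 1) ? M[i + 1][k - 1] : 0;
          int right = (k < j) ? M[k + 1][j] : 0;
          int cand = 1 + left + right;
          if (cand > best) best = cand;
        }
      }
      M[i][j] = best;
    }
  }

  // iterative traceback over intervals
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    std::pair<int, int> iv = stack.back();
    stack.pop_back();
    int i = iv.first, j = iv.second;
    if (i >= j || M[i][j] == 0) continue;
    if (M[i][j] == M[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (k - i > minLoop && canPair(seq[i], seq[k])) {
        int left = (k > i + 1) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        if (M[i][j] == 1 + left + right) {
          db[i] = '(';
          db[k] = ')';
          if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) stack.push_back(std::make_pair(k + 1, j));
          break;
        }
      }
    }
  }
  return List::create(_["dotbracket"] = db, _["pairs"] = M[0][n - 1]);
}
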