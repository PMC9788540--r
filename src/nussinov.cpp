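#include <Rcpp.h>
using namespace Rcpp;

// Maximum base-pairing (Nussinov) fold with a minimum hairpin loop size.
// Allowed pairs: AU, GC, GU (and reverses); anything else, including
// ambiguous bases, is unpairable.

static inline bool canpair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  for (size_t t = 0; t < seq.size(); ++t) {
    char c = (char) toupper(seq[t]);
    if (c == 'T') c = 'U';
    seq[t] = c;
  }
  std::vector< std::vector<int> > N(n + 2, std::vector<int>(n + 2, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      int best = N[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (canpair(seq[i - 1], seq[k - 1])) {
          int v = 1 + N[i + 1][k - 1] + (k < j ? N[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      N[i][j] = best;
    }
  }
  std::string db(n, '.');
  std::vector< std::pair<int, int> > todo;
  if (n > 0) todo.push_back(std::make_pair(1, n));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (N[i][j] == N[i + 1][j]) {
      todo.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (canpair(seq[i - 1], seq[k - 1])) {
        int v = 1 + N[i + 1][k - 1] + (k < j ? N[k + 1][j] : 0);
        if (v == N[i][j]) {
          db[i - 1] = '(';
          db[k - 1] = ')';
          todo.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) todo.push_back(std::make_pair(k + 1, j));
          break;
        }
      }
    }
  }
  int total = (n > 0) ? N[1][n] : 0;
  return List::create(_["pairs"] = total, _["structure"] = db);
}
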