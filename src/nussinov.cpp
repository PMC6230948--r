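#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Watson-Crick or G:U wobble pair; DNA/RNA alphabet (T treated as U)
static inline bool canPair(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum base pairing of a sequence against itself (Nussinov dynamic
// program, minimum loop size minLoop, G:U allowed), with one optimal
// structure recovered by traceback. Returns the pair list as a 2-column
// 0-based integer matrix (i < j) and the maximum pair count.
// [[Rcpp::export(name = ".nussinov")]]
List nussinov(std::string seq, int minLoop = 3) {
  const int n = (int) seq.size();
  if (n < 2) return List::create(_["max_pairs"] = 0,
                                 _["pairs"] = IntegerMatrix(0, 2));
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int span = minLoop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + minLoop + 1; k <= j; ++k) {
        if (canPair(seq[i], seq[k])) {
          int v = 1 + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                      (k < j ? dp[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      dp[i][j] = best;
    }
  }
  std::vector<std::pair<int, int> > todo, pairs;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i <= minLoop || dp[i][j] == 0) continue;
    if (dp[i][j] == dp[i + 1][j]) {
      todo.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + minLoop + 1; k <= j; ++k) {
      if (canPair(seq[i], seq[k])) {
        int v = 1 + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                    (k < j ? dp[k + 1][j] : 0);
        if (v == dp[i][j]) {
          pairs.push_back(std::make_pair(i, k));
          if (k > i + 1) todo.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) todo.push_back(std::make_pair(k + 1, j));
          break;
        }
      }
    }
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["max_pairs"] = dp[0][n - 1], _["pairs"] = pm);
}
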