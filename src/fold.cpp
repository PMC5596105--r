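#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weights: GC=3, AU=2, GU=1, else 0 (no pair).
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Maximum-weight nested pairing (weighted Nussinov) with hairpin loop >= min_loop.
// Recurrence over [i, j]: either j is unpaired, or j pairs with some k in [i, j - min_loop - 1],
// splitting into [i, k-1] and [k+1, j-1]. Traceback is deterministic: among equal-score
// options the pairing with the smallest k wins over leaving j unpaired.
// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0)
    return List::create(_["structure"] = db, _["score"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = pair_weight(seq[k], seq[j]);
        if (w == 0) continue;
        int s = w + (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (s > best) best = s;
      }
      M[i][j] = best;
    }
  }
  // traceback
  std::vector<std::pair<int,int>> pairs;
  std::vector<std::pair<int,int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    int target = M[i][j];
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      int w = pair_weight(seq[k], seq[j]);
      if (w == 0) continue;
      int s = w + (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (s == target) {
        pairs.push_back({k, j});
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back({i, k - 1});
        if (k + 1 <= j - 1) stack.push_back({k + 1, j - 1});
        done = true;
      }
    }
    if (!done) stack.push_back({i, j - 1});
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    pm(p, 0) = pairs[p].first + 1;  // 1-based for R
    pm(p, 1) = pairs[p].second + 1;
  }
  return List::create(_["structure"] = db, _["score"] = M[0][n - 1], _["pairs"] = pm);
}
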