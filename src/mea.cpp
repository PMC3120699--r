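// Maximum expected accuracy structure: Nussinov-style O(N^3) DP maximizing
//   score(S) = sum_{(i,j) in S} pair_weight * p(i,j) + sum_{i unpaired} q(i)
// over pseudoknot-free structures. Deterministic tie-breaking: the unpaired
// option is preferred on ties, then the pair with the smaller span (the k
// loop runs in ascending order and only a strict improvement replaces the
// incumbent).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".mea_cpp")]]
List mea_cpp(NumericMatrix P, NumericVector q, double pair_weight) {
  const int N = q.size();
  const int S = N + 2;
  auto id = [S](int i, int j) { return i * S + j; };
  std::vector<double> best(S * S, 0.0);
  std::vector<int> choice(S * S, 0);  // 0 = i unpaired, k > 0 = pair (i,k)

  for (int len = 1; len <= N; ++len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      double b = q[i - 1] + ((i + 1 <= j) ? best[id(i + 1, j)] : 0.0);
      int c = 0;
      for (int k = i + 1; k <= j; ++k) {
        double cand = pair_weight * P(i - 1, k - 1)
          + ((i + 1 <= k - 1) ? best[id(i + 1, k - 1)] : 0.0)
          + ((k + 1 <= j) ? best[id(k + 1, j)] : 0.0);
        if (cand > b) { b = cand; c = k; }
      }
      best[id(i, j)] = b;
      choice[id(i, j)] = c;
    }
  }

  std::vector<int> pi, pj;
  std::vector<std::pair<int, int>> stack;
  if (N >= 1) stack.push_back({1, N});
  while (!stack.empty()) {
    auto [i, j] = stack.back();
    stack.pop_back();
    if (i > j) continue;
    int c = choice[id(i, j)];
    if (c == 0) {
      if (i + 1 <= j) stack.push_back({i + 1, j});
    } else {
      pi.push_back(i); pj.push_back(c);
      if (i + 1 <= c - 1) stack.push_back({i + 1, c - 1});
      if (c + 1 <= j) stack.push_back({c + 1, j});
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t t = 0; t < pi.size(); ++t) {
    pairs(t, 0) = pi[t];
    pairs(t, 1) = pj[t];
  }
  return List::create(_["score"] = (N >= 1) ? best[id(1, N)] : 0.0,
                      _["pairs"] = pairs);
}
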