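// Pairwise alignment HMM: log-space forward/backward posteriors and Viterbi.
//
// States: 0 = ALN (consumes one residue of each sequence), 1 = INS1
// (consumes a residue of the first sequence only), 2 = INS2 (second only).
// A silent begin state enters the three states with a supplied initial
// distribution; ending is allowed from any state with no end factor.
// All recursions are in log space, so lattices for sequences of length 500+
// cannot underflow.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse3(double a, double b, double c) {
  double m = std::max(a, std::max(b, c));
  if (m == NEG_INF) return NEG_INF;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

struct Lattice {
  int n, m;
  std::vector<double> v;  // 3 states x (n+1) x (m+1)
  Lattice(int n_, int m_) : n(n_), m(m_), v(3 * (n_ + 1) * (m_ + 1), NEG_INF) {}
  double& at(int s, int i, int k) { return v[(s * (n + 1) + i) * (m + 1) + k]; }
  double at(int s, int i, int k) const { return v[(s * (n + 1) + i) * (m + 1) + k]; }
};

// Forward values: f(s, i, k) = log P(consume first i of x and k of y, last step in state s)
static void forward_fill(Lattice& f, const IntegerVector& x, const IntegerVector& y,
                         const NumericMatrix& lt, const NumericVector& li,
                         const NumericMatrix& lme, const NumericVector& lie) {
  int n = f.n, m = f.m;
  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k <= m; ++k) {
      if (i == 0 && k == 0) continue;
      // ALN lands at (i,k) from (i-1,k-1)
      if (i >= 1 && k >= 1) {
        double lp;
        if (i == 1 && k == 1) {
          lp = li[0];
        } else {
          lp = lse3(f.at(0, i - 1, k - 1) + lt(0, 0),
                    f.at(1, i - 1, k - 1) + lt(1, 0),
                    f.at(2, i - 1, k - 1) + lt(2, 0));
        }
        f.at(0, i, k) = lp + lme(x[i - 1], y[k - 1]);
      }
      // INS1 lands at (i,k) from (i-1,k)
      if (i >= 1) {
        double lp;
        if (i == 1 && k == 0) {
          lp = li[1];
        } else {
          lp = lse3(f.at(0, i - 1, k) + lt(0, 1),
                    f.at(1, i - 1, k) + lt(1, 1),
                    f.at(2, i - 1, k) + lt(2, 1));
        }
        f.at(1, i, k) = lp + lie[x[i - 1]];
      }
      // INS2 lands at (i,k) from (i,k-1)
      if (k >= 1) {
        double lp;
        if (i == 0 && k == 1) {
          lp = li[2];
        } else {
          lp = lse3(f.at(0, i, k - 1) + lt(0, 2),
                    f.at(1, i, k - 1) + lt(1, 2),
                    f.at(2, i, k - 1) + lt(2, 2));
        }
        f.at(2, i, k) = lp + lie[y[k - 1]];
      }
    }
  }
}

// [[Rcpp::export(name = ".hmm_posteriors_cpp")]]
List hmm_posteriors_cpp(IntegerVector x, IntegerVector y,
                        NumericMatrix lt, NumericVector li,
                        NumericMatrix lme, NumericVector lie) {
  int n = x.size(), m = y.size();
  Lattice f(n, m), b(n, m);
  forward_fill(f, x, y, lt, li, lme, lie);
  double loglik = lse3(f.at(0, n, m), f.at(1, n, m), f.at(2, n, m));

  // backward: b(s, i, k) = log P(consume the remainder | at (i,k) in state s)
  for (int s = 0; s < 3; ++s) b.at(s, n, m) = 0.0;
  for (int i = n; i >= 0; --i) {
    for (int k = m; k >= 0; --k) {
      if (i == n && k == m) continue;
      for (int s = 0; s < 3; ++s) {
        double ta = NEG_INF, t1 = NEG_INF, t2 = NEG_INF;
        if (i < n && k < m) ta = lt(s, 0) + lme(x[i], y[k]) + b.at(0, i + 1, k + 1);
        if (i < n) t1 = lt(s, 1) + lie[x[i]] + b.at(1, i + 1, k);
        if (k < m) t2 = lt(s, 2) + lie[y[k]] + b.at(2, i, k + 1);
        b.at(s, i, k) = lse3(ta, t1, t2);
      }
    }
  }

  NumericMatrix post_aln(n, m), post_ins1(n, m), post_ins2(n, m);
  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= m; ++k) {
      double pa = f.at(0, i, k) + b.at(0, i, k) - loglik;
      double p1 = f.at(1, i, k) + b.at(1, i, k) - loglik;
      double p2 = f.at(2, i, k) + b.at(2, i, k) - loglik;
      post_aln(i - 1, k - 1) = (pa == NEG_INF) ? 0.0 : std::exp(pa);
      post_ins1(i - 1, k - 1) = (p1 == NEG_INF) ? 0.0 : std::exp(p1);
      post_ins2(i - 1, k - 1) = (p2 == NEG_INF) ? 0.0 : std::exp(p2);
    }
  }
  return List::create(_["aln"] = post_aln, _["ins1"] = post_ins1,
                      _["ins2"] = post_ins2, _["loglik"] = loglik);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(IntegerVector x, IntegerVector y,
                     NumericMatrix lt, NumericVector li,
                     NumericMatrix lme, NumericVector lie) {
  int n = x.size(), m = y.size();
  Lattice v(n, m);
  std::vector<signed char> bt(3 * (n + 1) * (m + 1), -1);
  auto bti = [&](int s, int i, int k) -> signed char& {
    return bt[(s * (n + 1) + i) * (m + 1) + k];
  };
  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k <= m; ++k) {
      if (i == 0 && k == 0) continue;
      if (i >= 1 && k >= 1) {
        double best; signed char arg;
        if (i == 1 && k == 1) {
          best = li[0]; arg = -2;  // begin
        } else {
          best = NEG_INF; arg = -1;
          for (int s = 0; s < 3; ++s) {  // ties: first (lowest state index) wins
            double cand = v.at(s, i - 1, k - 1) + lt(s, 0);
            if (cand > best) { best = cand; arg = (signed char)s; }
          }
        }
        v.at(0, i, k) = best + lme(x[i - 1], y[k - 1]);
        bti(0, i, k) = arg;
      }
      if (i >= 1) {
        double best; signed char arg;
        if (i == 1 && k == 0) {
          best = li[1]; arg = -2;
        } else {
          best = NEG_INF; arg = -1;
          for (int s = 0; s < 3; ++s) {
            double cand = v.at(s, i - 1, k) + lt(s, 1);
            if (cand > best) { best = cand; arg = (signed char)s; }
          }
        }
        v.at(1, i, k) = best + lie[x[i - 1]];
        bti(1, i, k) = arg;
      }
      if (k >= 1) {
        double best; signed char arg;
        if (i == 0 && k == 1) {
          best = li[2]; arg = -2;
        } else {
          best = NEG_INF; arg = -1;
          for (int s = 0; s < 3; ++s) {
            double cand = v.at(s, i, k - 1) + lt(s, 2);
            if (cand > best) { best = cand; arg = (signed char)s; }
          }
        }
        v.at(2, i, k) = best + lie[y[k - 1]];
        bti(2, i, k) = arg;
      }
    }
  }
  double best = NEG_INF; int s = -1;
  for (int t = 0; t < 3; ++t) {
    if (v.at(t, n, m) > best) { best = v.at(t, n, m); s = t; }
  }
  // traceback
  std::vector<int> states, is, ks;
  int i = n, k = m;
  while (true) {
    states.push_back(s); is.push_back(i); ks.push_back(k);
    signed char prev = bti(s, i, k);
    int pi = i, pk = k;
    if (s == 0) { pi = i - 1; pk = k - 1; }
    else if (s == 1) { pi = i - 1; }
    else { pk = k - 1; }
    if (prev == -2) break;  // reached the begin state
    s = prev; i = pi; k = pk;
  }
  int L = states.size();
  IntegerMatrix path(L, 3);
  for (int t = 0; t < L; ++t) {
    path(t, 0) = states[L - 1 - t] + 1;  // 1=ALN, 2=INS1, 3=INS2
    path(t, 1) = is[L - 1 - t];
    path(t, 2) = ks[L - 1 - t];
  }
  colnames(path) = CharacterVector::create("state", "i", "k");
  return List::create(_["path"] = path, _["logprob"] = best);
}
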