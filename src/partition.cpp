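// Modified partition function over pseudoknot-free canonical structures.
//
// Inside/outside dynamic programming under the simplified nearest-neighbor
// model, with a per-pair multiplicative prior w(i,j) = ext(i,j)^(gamma/RT)
// (equivalently a pseudo-free-energy -gamma * ln ext(i,j) added per pair).
// Grammar (unambiguous; every structure is generated exactly once):
//   V(i,j)  : subsequence i..j closed by pair (i,j); hairpin, interior
//             (stack/bulge/internal, total unpaired <= maxloop), or
//             multibranch closing via M * M1.
//   M(i,j)  : multibranch segment with >= 1 branch.
//   M1(i,j) : multibranch segment whose single branch starts at i
//             (trailing unpaired allowed).
//   W       : exterior prefix; Wr : exterior suffix.
// Accumulation in long double: at N = 500 the largest Boltzmann exponents
// stay far inside the 80-bit extended range, so no rescaling is needed.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

typedef long double ld;

// pair type codes: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5 ; -1 = not canonical
// residue codes: A=0, C=1, G=2, U=3
static inline int ptcode(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// [[Rcpp::export(name = ".partition_cpp")]]
List partition_cpp(IntegerVector seq, NumericMatrix ext, double gamma,
                   double eps_ext, double RT, int minhp, int maxloop,
                   NumericMatrix stackE, NumericVector hairpinE,
                   NumericVector bulgeE, NumericVector internalE,
                   double ml_a, double ml_b, double ml_c,
                   NumericVector aupen) {
  const int N = seq.size();
  const int S = N + 2;
  auto id = [S](int i, int j) { return i * S + j; };

  std::vector<int> pt(S * S, -1);
  for (int i = 1; i <= N; ++i)
    for (int j = i + 1; j <= N; ++j)
      pt[id(i, j)] = ptcode(seq[i - 1], seq[j - 1]);

  // precomputed Boltzmann factors
  std::vector<ld> estack(36), eaup(6), ebranch(6);
  for (int p = 0; p < 6; ++p) {
    eaup[p] = expl(-(ld)aupen[p] / RT);
    ebranch[p] = expl(-((ld)ml_b + aupen[p]) / RT);  // per-branch cost + terminal penalty
    for (int q = 0; q < 6; ++q) estack[p * 6 + q] = expl(-(ld)stackE(p, q) / RT);
  }
  std::vector<ld> ehp(N + 1, 0.0L), ebul(maxloop + 1, 0.0L), eint(maxloop + 1, 0.0L);
  for (int n = 0; n <= N; ++n) ehp[n] = expl(-(ld)hairpinE[n] / RT);
  for (int n = 1; n <= maxloop; ++n) ebul[n] = expl(-(ld)bulgeE[n] / RT);
  for (int n = 2; n <= maxloop; ++n) eint[n] = expl(-(ld)internalE[n] / RT);
  const ld ec = expl(-(ld)ml_c / RT);
  std::vector<ld> ecpow(N + 2);
  ecpow[0] = 1.0L;
  for (int d = 1; d <= N + 1; ++d) ecpow[d] = ecpow[d - 1] * ec;

  // pair prior; gamma = 0 gives w = 1 exactly
  const ld gexp = (ld)gamma / RT;
  std::vector<ld> w(S * S, 0.0L);
  for (int i = 1; i <= N; ++i) {
    for (int j = i + 1; j <= N; ++j) {
      ld e = (ld)ext(i - 1, j - 1);
      if (e < (ld)eps_ext) e = (ld)eps_ext;
      w[id(i, j)] = (gamma == 0.0) ? 1.0L : powl(e, gexp);
    }
  }

  std::vector<ld> V(S * S, 0.0L), M(S * S, 0.0L), M1(S * S, 0.0L);
  auto interior_factor = [&](int i, int j, int k, int l) -> ld {
    // loop closed by (i,j) with inner pair (k,l); includes terminal penalties
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0) return estack[pt[id(i, j)] * 6 + pt[id(k, l)]];
    ld lf = (n1 == 0 || n2 == 0) ? ebul[n1 + n2] : eint[n1 + n2];
    return lf * eaup[pt[id(i, j)]] * eaup[pt[id(k, l)]];
  };

  const ld e_mlclose = expl(-((ld)ml_a + ml_b) / RT);  // closing pair's a + b share

  for (int len = 1; len <= N; ++len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      int ptij = pt[id(i, j)];
      // V
      if (len >= minhp + 2 && ptij >= 0) {
        ld acc = ehp[len - 2] * eaup[ptij];  // hairpin
        for (int k = i + 1; k <= j - 1 && k - i - 1 <= maxloop; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + minhp + 1, j - 1 - (maxloop - n1));
          for (int l = j - 1; l >= lmin; --l) {
            ld vkl = V[id(k, l)];
            if (vkl > 0.0L) acc += interior_factor(i, j, k, l) * vkl;
          }
        }
        if (len >= minhp + 4) {  // room for two branches
          ld mlacc = 0.0L;
          for (int u = i + 2; u <= j - 2; ++u)
            mlacc += M[id(i + 1, u - 1)] * M1[id(u, j - 1)];
          acc += e_mlclose * eaup[ptij] * mlacc;
        }
        V[id(i, j)] = w[id(i, j)] * acc;
      }
      // M1 (branch starts at i, trailing unpaired)
      ld m1 = (j > i) ? M1[id(i, j - 1)] * ec : 0.0L;
      if (V[id(i, j)] > 0.0L) m1 += V[id(i, j)] * ebranch[ptij];
      M1[id(i, j)] = m1;
      // M (>= 1 branch)
      ld m = (j > i) ? M[id(i, j - 1)] * ec : 0.0L;
      for (int k = i; k <= j; ++k) {
        ld vkj = V[id(k, j)];
        if (vkj > 0.0L) {
          ld prefix = ecpow[k - i] + ((k > i) ? M[id(i, k - 1)] : 0.0L);
          m += prefix * vkj * ebranch[pt[id(k, j)]];
        }
      }
      M[id(i, j)] = m;
    }
  }

  // exterior prefix/suffix
  std::vector<ld> W(N + 2, 0.0L), Wr(N + 3, 0.0L);
  W[0] = 1.0L;
  for (int j = 1; j <= N; ++j) {
    W[j] = W[j - 1];
    for (int i = 1; i < j; ++i) {
      ld vij = V[id(i, j)];
      if (vij > 0.0L) W[j] += W[i - 1] * vij * eaup[pt[id(i, j)]];
    }
  }
  Wr[N + 1] = 1.0L;
  for (int i = N; i >= 1; --i) {
    Wr[i] = Wr[i + 1];
    for (int j = i + 1; j <= N; ++j) {
      ld vij = V[id(i, j)];
      if (vij > 0.0L) Wr[i] += vij * eaup[pt[id(i, j)]] * Wr[j + 1];
    }
  }
  const ld Z = W[N];

  // outside pass, longest spans first; within a span M and M1 productions
  // feed the same-span hatV before V's own productions are expanded
  std::vector<ld> hV(S * S, 0.0L), hM(S * S, 0.0L), hM1(S * S, 0.0L);
  for (int i = 1; i <= N; ++i)
    for (int j = i + 1; j <= N; ++j)
      if (V[id(i, j)] > 0.0L)
        hV[id(i, j)] = W[i - 1] * Wr[j + 1] * eaup[pt[id(i, j)]];

  for (int len = N; len >= 1; --len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      // M productions
      ld hm = hM[id(i, j)];
      if (hm > 0.0L) {
        if (j > i) hM[id(i, j - 1)] += hm * ec;
        for (int k = i; k <= j; ++k) {
          ld vkj = V[id(k, j)];
          if (vkj > 0.0L) {
            ld prefix = ecpow[k - i] + ((k > i) ? M[id(i, k - 1)] : 0.0L);
            hV[id(k, j)] += hm * prefix * ebranch[pt[id(k, j)]];
            if (k > i) hM[id(i, k - 1)] += hm * vkj * ebranch[pt[id(k, j)]];
          }
        }
      }
      // M1 productions
      ld h1 = hM1[id(i, j)];
      if (h1 > 0.0L) {
        if (j > i) hM1[id(i, j - 1)] += h1 * ec;
        if (V[id(i, j)] > 0.0L) hV[id(i, j)] += h1 * ebranch[pt[id(i, j)]];
      }
      // V productions
      int ptij = pt[id(i, j)];
      if (len >= minhp + 2 && ptij >= 0) {
        ld hv = hV[id(i, j)];
        if (hv > 0.0L) {
          ld hvw = hv * w[id(i, j)];
          for (int k = i + 1; k <= j - 1 && k - i - 1 <= maxloop; ++k) {
            int n1 = k - i - 1;
            int lmin = std::max(k + minhp + 1, j - 1 - (maxloop - n1));
            for (int l = j - 1; l >= lmin; --l) {
              if (V[id(k, l)] > 0.0L)
                hV[id(k, l)] += hvw * interior_factor(i, j, k, l);
            }
          }
          if (len >= minhp + 4) {
            ld base = hvw * e_mlclose * eaup[ptij];
            for (int u = i + 2; u <= j - 2; ++u) {
              hM[id(i + 1, u - 1)] += base * M1[id(u, j - 1)];
              hM1[id(u, j - 1)] += base * M[id(i + 1, u - 1)];
            }
          }
        }
      }
    }
  }

  NumericMatrix probs(N, N);
  for (int i = 1; i <= N; ++i) {
    for (int j = i + 1; j <= N; ++j) {
      ld vij = V[id(i, j)];
      if (vij > 0.0L) {
        ld p = vij * hV[id(i, j)] / Z;
        if (p < 0.0L) p = 0.0L;
        if (p > 1.0L) p = 1.0L;
        probs(i - 1, j - 1) = (double)p;
        probs(j - 1, i - 1) = (double)p;
      }
    }
  }
  double lnZ = (double)logl(Z);
  return List::create(_["probs"] = probs, _["lnZ"] = lnZ);
}
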