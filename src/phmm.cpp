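#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local (Smith-Waterman-style entry/exit) profile-HMM dynamic programming
// in log-odds space. States per node k: match M_k, insert I_k, delete D_k.
// A local path enters at any match state at any sequence position
// (probability 1/(M*L): uniform over entry states and start positions)
// and exits after any match state (1/M); flanking residues are scored by
// the background and contribute zero in log-odds. This ensemble is a
// probability subdensity, so background sequences score <= 0 on average.
// Transition columns, in order: 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD
// (natural log).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

static inline double emit(const NumericMatrix& lod, int k, int x) {
  // x is 0-based residue index, -1 for unknown (background emission)
  return x < 0 ? 0.0 : lod(k, x);
}

// [[Rcpp::export]]
double phmm_forward(NumericMatrix lodM, NumericMatrix lodI,
                    NumericMatrix ltr, IntegerVector seq) {
  const int M = lodM.nrow();
  const int L = seq.size();
  const double entry = -std::log((double)M) - std::log((double)L);
  const double exitp = -std::log((double)M);

  std::vector<double> fmPrev(M, NEG_INF), fiPrev(M, NEG_INF),
      fdPrev(M, NEG_INF), fm(M), fi(M), fd(M);
  double total = NEG_INF;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i] - 1;  // -1 => unknown
    for (int k = 0; k < M; ++k) {
      double from = entry;  // fresh local entry at M_k
      if (k > 0) {
        from = lse2(from, lse3(fmPrev[k - 1] + ltr(k - 1, 0),
                               fiPrev[k - 1] + ltr(k - 1, 3),
                               fdPrev[k - 1] + ltr(k - 1, 5)));
      }
      fm[k] = emit(lodM, k, x) + from;
      fi[k] = emit(lodI, k, x) +
              lse2(fmPrev[k] + ltr(k, 1), fiPrev[k] + ltr(k, 4));
      fd[k] = (k > 0)
          ? lse2(fm[k - 1] + ltr(k - 1, 2), fd[k - 1] + ltr(k - 1, 6))
          : NEG_INF;
      total = lse2(total, fm[k] + exitp);
    }
    fmPrev = fm; fiPrev = fi; fdPrev = fd;
  }
  return total / std::log(2.0);  // bits
}

// [[Rcpp::export]]
List phmm_viterbi(NumericMatrix lodM, NumericMatrix lodI,
                  NumericMatrix ltr, IntegerVector seq) {
  const int M = lodM.nrow();
  const int L = seq.size();
  const double entry = -std::log((double)M) - std::log((double)L);
  const double exitp = -std::log((double)M);

  // DP tables over (position, node) for the three state types.
  // Backpointers: 0 entry, 1 from M, 2 from I, 3 from D.
  std::vector<double> vm(L * M, NEG_INF), vi(L * M, NEG_INF),
      vd(L * M, NEG_INF);
  std::vector<signed char> bm(L * M, 0), bi(L * M, 0), bd(L * M, 0);
  auto id = [M](int i, int k) { return i * M + k; };

  double best = NEG_INF;
  int bestI = -1, bestK = -1;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i] - 1;
    for (int k = 0; k < M; ++k) {
      // match
      double from = entry; signed char ptr = 0;
      if (k > 0 && i > 0) {
        double fM = vm[id(i - 1, k - 1)] + ltr(k - 1, 0);
        double fI = vi[id(i - 1, k - 1)] + ltr(k - 1, 3);
        double fD = vd[id(i - 1, k - 1)] + ltr(k - 1, 5);
        // tie-break preference M > I > D (>= comparisons)
        if (fM >= from) { from = fM; ptr = 1; }
        if (fI > from) { from = fI; ptr = 2; }
        if (fD > from) { from = fD; ptr = 3; }
      } else if (k > 0) {
        // i == 0: only entry possible
      }
      vm[id(i, k)] = emit(lodM, k, x) + from;
      bm[id(i, k)] = ptr;
      // insert
      if (i > 0) {
        double fM = vm[id(i - 1, k)] + ltr(k, 1);
        double fI = vi[id(i - 1, k)] + ltr(k, 4);
        if (fM >= fI) { vi[id(i, k)] = emit(lodI, k, x) + fM; bi[id(i, k)] = 1; }
        else { vi[id(i, k)] = emit(lodI, k, x) + fI; bi[id(i, k)] = 2; }
      }
      // delete (no emission, same position)
      if (k > 0) {
        double fM = vm[id(i, k - 1)] + ltr(k - 1, 2);
        double fD = vd[id(i, k - 1)] + ltr(k - 1, 6);
        if (fM >= fD) { vd[id(i, k)] = fM; bd[id(i, k)] = 1; }
        else { vd[id(i, k)] = fD; bd[id(i, k)] = 3; }
      }
      double sc = vm[id(i, k)] + exitp;
      if (sc > best) { best = sc; bestI = i; bestK = k; }
    }
  }

  std::vector<int> nodes, poss;
  if (bestI >= 0) {
    int i = bestI, k = bestK, st = 1;  // 1 = M, 2 = I, 3 = D
    while (true) {
      if (st == 1) {
        nodes.push_back(k + 1); poss.push_back(i + 1);
        signed char p = bm[id(i, k)];
        if (p == 0) break;
        st = p; --i; --k;
      } else if (st == 2) {
        signed char p = bi[id(i, k)];
        st = p; --i;
      } else {
        signed char p = bd[id(i, k)];
        st = p; --k;
      }
    }
  }
  const int n = nodes.size();
  IntegerVector node(n), pos(n);
  for (int t = 0; t < n; ++t) {  // reverse into sequence order
    node[t] = nodes[n - 1 - t];
    pos[t] = poss[n - 1 - t];
  }
  return List::create(_["score"] = best / std::log(2.0),
                      _["node"] = node, _["pos"] = pos);
}
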