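#include <Rcpp.h>
using namespace Rcpp;

// Local (single-hit) Viterbi and Forward for a simplified Plan7 profile HMM,
// all in log2-odds space. Entry into any match node costs log2(1/M), exit
// from any match node costs log2(1/M); flanking sequence residues are
// unmodeled (log-odds 0 against the background null).
//
// Arguments (all log2):
//   lm  : M x A match emission log-odds, lm(k, a) = log2(e_k(a) / bg(a))
//   li  : M x A insert emission log-odds (usually 0)
//   tr  : M x 7 transitions, columns MM MI MD IM II DM DD; row k holds the
//         transitions out of node k (MM/MD/DM/DD lead to node k+1).
//   x   : sequence as 0-based codes into the emission columns.
// Returns Viterbi bit score plus envelope (1-based closed) and node span.

static const double NEG = -1e30;

// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(NumericMatrix lm, NumericMatrix li, NumericMatrix tr,
                  IntegerVector x) {
  const int M = lm.nrow(), L = x.size();
  const double entry = -log2((double)M), exitc = -log2((double)M);
  if (L == 0 || M == 0)
    return List::create(_["score"] = NA_REAL);
  NumericMatrix VM(L + 1, M + 1), VI(L + 1, M + 1), VD(L + 1, M + 1);
  // ptr codes: for M: 0 entry, 1 from M, 2 from I, 3 from D
  IntegerMatrix pM(L + 1, M + 1), pI(L + 1, M + 1), pD(L + 1, M + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  double best = NEG; int bj = -1, bk = -1;
  for (int j = 1; j <= L; ++j) {
    const int a = x[j - 1];
    for (int k = 1; k <= M; ++k) {
      // match
      double cand = entry; int p = 0;
      if (k > 1) {
        double vm = VM(j - 1, k - 1) + tr(k - 2, 0);
        double vi = VI(j - 1, k - 1) + tr(k - 2, 3);
        double vd = VD(j - 1, k - 1) + tr(k - 2, 5);
        if (vm > cand) { cand = vm; p = 1; }
        if (vi > cand) { cand = vi; p = 2; }
        if (vd > cand) { cand = vd; p = 3; }
      }
      VM(j, k) = cand + lm(k - 1, a);
      pM(j, k) = p;
      // insert (between node k and k+1; only k < M meaningful)
      if (k < M) {
        double im = VM(j - 1, k) + tr(k - 1, 1);
        double ii = VI(j - 1, k) + tr(k - 1, 4);
        if (im >= ii) { VI(j, k) = im + li(k - 1, a); pI(j, k) = 1; }
        else          { VI(j, k) = ii + li(k - 1, a); pI(j, k) = 2; }
      }
      // delete
      if (k > 1) {
        double dm = VM(j, k - 1) + tr(k - 2, 2);
        double dd = VD(j, k - 1) + tr(k - 2, 6);
        if (dm >= dd) { VD(j, k) = dm; pD(j, k) = 1; }
        else          { VD(j, k) = dd; pD(j, k) = 2; }
      }
      double sc = VM(j, k) + exitc;
      if (sc > best) { best = sc; bj = j; bk = k; }
    }
  }
  // traceback from (bj, bk) in M state
  int j = bj, k = bk, st = 0; // 0 = M, 1 = I, 2 = D
  int env_end = bj, node_end = bk, env_start = bj, node_start = bk;
  int nmatch = 0;
  while (true) {
    if (st == 0) {
      env_start = j; node_start = k; ++nmatch;
      int p = pM(j, k);
      if (p == 0) break;
      --j; --k;
      st = (p == 1) ? 0 : (p == 2 ? 1 : 2);
    } else if (st == 1) {
      int p = pI(j, k);
      --j;
      st = (p == 1) ? 0 : 1;
    } else {
      int p = pD(j, k);
      --k;
      st = (p == 1) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best,
                      _["env_start"] = env_start, _["env_end"] = env_end,
                      _["node_start"] = node_start, _["node_end"] = node_end,
                      _["n_match"] = nmatch);
}

static inline double lse2(double a, double b) {
  if (a == NEG && b == NEG) return NEG;
  double m = std::max(a, b);
  return m + log2(exp2(a - m) + exp2(b - m));
}

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(NumericMatrix lm, NumericMatrix li, NumericMatrix tr,
                    IntegerVector x) {
  const int M = lm.nrow(), L = x.size();
  const double entry = -log2((double)M), exitc = -log2((double)M);
  if (L == 0 || M == 0) return NA_REAL;
  NumericMatrix FM(L + 1, M + 1), FI(L + 1, M + 1), FD(L + 1, M + 1);
  std::fill(FM.begin(), FM.end(), NEG);
  std::fill(FI.begin(), FI.end(), NEG);
  std::fill(FD.begin(), FD.end(), NEG);
  double total = NEG;
  for (int j = 1; j <= L; ++j) {
    const int a = x[j - 1];
    for (int k = 1; k <= M; ++k) {
      double cand = entry;
      if (k > 1) {
        cand = lse2(cand, FM(j - 1, k - 1) + tr(k - 2, 0));
        cand = lse2(cand, FI(j - 1, k - 1) + tr(k - 2, 3));
        cand = lse2(cand, FD(j - 1, k - 1) + tr(k - 2, 5));
      }
      FM(j, k) = cand + lm(k - 1, a);
      if (k < M)
        FI(j, k) = lse2(FM(j - 1, k) + tr(k - 1, 1),
                        FI(j - 1, k) + tr(k - 1, 4)) + li(k - 1, a);
      if (k > 1)
        FD(j, k) = lse2(FM(j, k - 1) + tr(k - 2, 2),
                        FD(j, k - 1) + tr(k - 2, 6));
      total = lse2(total, FM(j, k) + exitc);
    }
  }
  return total;
}
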