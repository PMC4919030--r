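#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps for the progressive
// aligner. Profiles are (ncol x (A+1)) count matrices: residue counts in the
// first A columns, gap count in the last. Column-pair score is the
// average-of-pairs substitution score; residue-vs-gap scores gap_extend
// (negative), gap-gap scores 0. Opening a new inter-profile gap additionally
// costs |gap_open|. End gaps are penalized (true global alignment).
//
// Returns a merge path: 1 = column from A and B, 2 = A only (gap in B),
// 3 = B only (gap in A).

// [[Rcpp::export(name = ".profile_align")]]
IntegerVector profile_align(NumericMatrix A, NumericMatrix B,
                            NumericMatrix sub, double gap_open,
                            double gap_extend) {
  const int n = A.nrow(), m = B.nrow(), R = sub.nrow();
  const double NEG = -1e30;
  // effective sequence counts per profile
  double nA = 0, nB = 0;
  for (int r = 0; r <= R; ++r) { nA += A(0, r); nB += B(0, r); }
  // precompute column-pair scores
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double sc = 0;
      for (int r = 0; r < R; ++r) {
        if (A(i, r) == 0) continue;
        for (int s = 0; s < R; ++s)
          if (B(j, s) > 0) sc += A(i, r) * B(j, s) * sub(r, s);
        sc += A(i, r) * B(j, R) * gap_extend; // residue in A vs gap in B
      }
      for (int s = 0; s < R; ++s)
        if (B(j, s) > 0) sc += A(i, R) * B(j, s) * gap_extend;
      S(i, j) = sc / (nA * nB);
    }
  const double go = gap_open + gap_extend;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix pH(n + 1, m + 1), pE(n + 1, m + 1), pF(n + 1, m + 1);
  H(0, 0) = 0; E(0, 0) = F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -go - gap_extend * (j - 1);
    H(0, j) = E(0, j); F(0, j) = NEG;
    pH(0, j) = 3; pE(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -go - gap_extend * (i - 1);
    H(i, 0) = F(i, 0); E(i, 0) = NEG;
    pH(i, 0) = 2; pF(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double eo = H(i, j - 1) - go, ee = E(i, j - 1) - gap_extend;
      if (eo >= ee) { E(i, j) = eo; pE(i, j) = 0; } else { E(i, j) = ee; pE(i, j) = 1; }
      double fo = H(i - 1, j) - go, fe = F(i - 1, j) - gap_extend;
      if (fo >= fe) { F(i, j) = fo; pF(i, j) = 0; } else { F(i, j) = fe; pF(i, j) = 1; }
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = std::max(d, std::max(E(i, j), F(i, j)));
      int p;
      if (h == d) p = 1; else if (h == F(i, j)) p = 2; else p = 3;
      H(i, j) = h; pH(i, j) = p;
    }
  // traceback
  std::vector<int> path;
  int i = n, j = m, st = 0;
  while (i > 0 || j > 0) {
    if (st == 0) {
      int p = pH(i, j);
      if (p == 1) { path.push_back(1); --i; --j; }
      else st = p;
    } else if (st == 2) {
      path.push_back(2);
      int p = pF(i, j); --i;
      if (p == 0) st = 0;
    } else {
      path.push_back(3);
      int p = pE(i, j); --j;
      if (p == 0) st = 0;
    }
  }
  std::reverse(path.begin(), path.end());
  return IntegerVector(path.begin(), path.end());
}
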