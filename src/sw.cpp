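#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Sequences arrive as 0-based integer
// codes into the scoring matrix; a gap of length k costs open + k * extend
// (FASTA/PRSS convention, both penalties positive here).
//
// Tie-breaks, fixed for reproducibility: diagonal > subject-gap (query
// residue consumed) > query-gap; among equal-scoring end cells the smallest
// (query_end, subject_end) wins lexicographically.

static inline double col_max4(double a, double b, double c, double d) {
  return std::max(std::max(a, b), std::max(c, d));
}

// [[Rcpp::export(name = ".sw_score")]]
int sw_score(IntegerVector q, IntegerVector s, IntegerMatrix sub,
             int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) return 0;
  const int go = gap_open + gap_extend; // cost of first gapped residue
  std::vector<int> H(m + 1, 0), E(m + 1, INT_MIN / 2);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0, F = INT_MIN / 2, Hprev = 0; // H[i][0] = 0
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - go, E[j] - gap_extend);           // gap in query
      F    = std::max(Hprev - go, F - gap_extend);             // gap in subject
      int h = diag + sub(q[i - 1], s[j - 1]);
      h = std::max(std::max(h, E[j]), std::max(F, 0));
      diag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with traceback. Returns score, 1-based closed intervals, and the
// column states (0 match, 1 mismatch, 2 query-gap, 3 subject-gap).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector s, IntegerMatrix sub,
              int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = -1,
                        _["s_start"] = 0, _["s_end"] = -1,
                        _["states"] = IntegerVector(0));
  const int go = gap_open + gap_extend;
  const double NEG = -1e18;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // ptrH: 0 stop, 1 diag, 2 from F (subject-gap), 3 from E (query-gap)
  IntegerMatrix ptrH(n + 1, m + 1), ptrE(n + 1, m + 1), ptrF(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H(i, j - 1) - go, ee = E(i, j - 1) - gap_extend;
      if (eo >= ee) { E(i, j) = eo; ptrE(i, j) = 0; } else { E(i, j) = ee; ptrE(i, j) = 1; }
      double fo = H(i - 1, j) - go, fe = F(i - 1, j) - gap_extend;
      if (fo >= fe) { F(i, j) = fo; ptrF(i, j) = 0; } else { F(i, j) = fe; ptrF(i, j) = 1; }
      double d = H(i - 1, j - 1) + sub(q[i - 1], s[j - 1]);
      double h = col_max4(d, F(i, j), E(i, j), 0.0);
      int p;
      if (h <= 0.0) p = 0;             // fresh start: a zero cell ends the path
      else if (h == d) p = 1;          // diagonal preferred
      else if (h == F(i, j)) p = 2;    // then subject-gap
      else p = 3;                      // then query-gap
      H(i, j) = h; ptrH(i, j) = p;
      if (h > best) { best = h; bi = i; bj = j; } // first (smallest i, then j) kept on ties
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = -1,
                        _["s_start"] = 0, _["s_end"] = -1,
                        _["states"] = IntegerVector(0));
  // traceback
  std::vector<int> states;
  int i = bi, j = bj, state = 0; // 0 in H, 2 in F, 3 in E
  while (true) {
    if (state == 0) {
      int p = ptrH(i, j);
      if (p == 0) break;
      if (p == 1) {
        states.push_back(q[i - 1] == s[j - 1] ? 0 : 1);
        --i; --j;
      } else state = p;
    } else if (state == 2) { // subject-gap: consumes query residue
      states.push_back(3);
      int p = ptrF(i, j);
      --i;
      if (p == 0) state = 0;
    } else { // state == 3, query-gap: consumes subject residue
      states.push_back(2);
      int p = ptrE(i, j);
      --j;
      if (p == 0) state = 0;
    }
  }
  std::reverse(states.begin(), states.end());
  return List::create(_["score"] = (int)best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj,
                      _["states"] = IntegerVector(states.begin(), states.end()));
}
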