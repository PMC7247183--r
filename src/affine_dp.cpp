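#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap alignment (Gotoh) over a precomputed column-score matrix.
//
// C(i,j) = score of aligning element i of A (rows) with element j of B.
// A gap run of length L costs gap_open + (L-1) * gap_ext (both <= 0).
// local = true gives best-scoring sub-path (Smith-Waterman), local score
// never negative; local optima end on an aligned pair. Traceback ties are
// resolved diagonal > up (gap in B) > left (gap in A) for reproducibility.
//
// Returns list(score, a_idx, b_idx): parallel 1-based index vectors with 0
// marking a gap position.
// [[Rcpp::export]]
List affine_dp_cpp(NumericMatrix C, double gap_open, double gap_ext,
                   bool local) {
  const int m = C.nrow(), n = C.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state 0 = M (aligned pair), 1 = X (A vs gap, "up"), 2 = Y (gap vs B)
  std::vector<double> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  // backpointer: predecessor state (0,1,2) or 3 = fresh start / origin
  std::vector<unsigned char> bM((m + 1) * (n + 1), 3),
      bX((m + 1) * (n + 1), 3), bY((m + 1) * (n + 1), 3);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_ext;
    bX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_ext;
    bY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  if (local) {
    for (int i = 0; i <= m; ++i) M[at(i, 0)] = (i == 0) ? 0.0 : NEG;
    for (int i = 0; i <= m; ++i) X[at(i, 0)] = NEG;
    for (int j = 0; j <= n; ++j) Y[at(0, j)] = NEG;
  }

  double best = local ? 0.0 : NEG;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: from M/X/Y diagonal predecessor (ties: M > X > Y), local may
      // start fresh when all predecessors are <= 0.
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double pre = dM; unsigned char bp = 0;
      if (dX > pre) { pre = dX; bp = 1; }
      if (dY > pre) { pre = dY; bp = 2; }
      if (local && pre < 0.0) { pre = 0.0; bp = 3; }
      M[at(i, j)] = pre + C(i - 1, j - 1);
      bM[at(i, j)] = bp;

      // X: consume A[i] against a gap
      double xo = M[at(i - 1, j)] + gap_open, xe = X[at(i - 1, j)] + gap_ext,
             xy = Y[at(i - 1, j)] + gap_open;
      double xv = xo; unsigned char xb = 0;
      if (xe > xv) { xv = xe; xb = 1; }
      if (xy > xv) { xv = xy; xb = 2; }
      X[at(i, j)] = xv; bX[at(i, j)] = xb;

      // Y: consume B[j] against a gap
      double yo = M[at(i, j - 1)] + gap_open, yx = X[at(i, j - 1)] + gap_open,
             ye = Y[at(i, j - 1)] + gap_ext;
      double yv = yo; unsigned char yb = 0;
      if (yx > yv) { yv = yx; yb = 1; }
      if (ye > yv) { yv = ye; yb = 2; }
      Y[at(i, j)] = yv; bY[at(i, j)] = yb;

      if (local && M[at(i, j)] > best) {
        best = M[at(i, j)]; best_i = i; best_j = j;
      }
    }
  }

  std::vector<int> ai, bi;
  double score;
  if (local) {
    score = best;
    if (best_i > 0) {
      int i = best_i, j = best_j, st = 0;
      while (true) {
        if (st == 0) {
          unsigned char bp = bM[at(i, j)];
          ai.push_back(i); bi.push_back(j);
          --i; --j;
          if (bp == 3) break;
          st = bp;
          if (i == 0 && j == 0) break;
        } else if (st == 1) {
          ai.push_back(i); bi.push_back(0);
          st = bX[at(i, j)]; --i;
        } else {
          ai.push_back(0); bi.push_back(j);
          st = bY[at(i, j)]; --j;
        }
      }
    }
  } else {
    double vM = M[at(m, n)], vX = X[at(m, n)], vY = Y[at(m, n)];
    int st = 0; score = vM;
    if (vX > score) { score = vX; st = 1; }
    if (vY > score) { score = vY; st = 2; }
    int i = m, j = n;
    while (i > 0 || j > 0) {
      if (st == 0) {
        unsigned char bp = bM[at(i, j)];
        ai.push_back(i); bi.push_back(j);
        --i; --j; st = bp;
      } else if (st == 1) {
        unsigned char bp = bX[at(i, j)];
        ai.push_back(i); bi.push_back(0);
        --i; st = bp;
      } else {
        unsigned char bp = bY[at(i, j)];
        ai.push_back(0); bi.push_back(j);
        --j; st = bp;
      }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
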