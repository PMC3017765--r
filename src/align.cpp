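#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP,
// over a precomputed column-vs-column score matrix S (n x m). A gap run of
// length k costs open + (k-1) * ext (open and ext are <= 0 penalties).
// Tie-breaking is deterministic: diagonal (match state M), then up (gap in B,
// state X), then left (gap in A, state Y), applied both when maximising each
// cell and at traceback.
//
// Returns the optimal score and the alignment path encoded 0 = diagonal,
// 1 = up (consume a column of A), 2 = left (consume a column of B).

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  // predecessor state per cell per matrix: 0=M, 1=X, 2=Y
  std::vector<signed char> pM((n + 1) * w, -1), pX((n + 1) * w, -1),
      pY((n + 1) * w, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = open + (i - 1) * ext;
    pX[i * w] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = open + (j - 1) * ext;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * w + j, d = (i - 1) * w + (j - 1);
      const int u = (i - 1) * w + j, l = i * w + (j - 1);
      // M: from any state at (i-1, j-1), prefer M > X > Y on ties
      {
        double best = M[d]; signed char from = 0;
        if (X[d] > best) { best = X[d]; from = 1; }
        if (Y[d] > best) { best = Y[d]; from = 2; }
        M[c] = best + S(i - 1, j - 1);
        pM[c] = from;
      }
      // X: consume A row i (gap in B)
      {
        double best = M[u] + open; signed char from = 0;
        if (X[u] + ext > best) { best = X[u] + ext; from = 1; }
        if (Y[u] + open > best) { best = Y[u] + open; from = 2; }
        X[c] = best;
        pX[c] = from;
      }
      // Y: consume B column j (gap in A)
      {
        double best = M[l] + open; signed char from = 0;
        if (X[l] + open > best) { best = X[l] + open; from = 1; }
        if (Y[l] + ext > best) { best = Y[l] + ext; from = 2; }
        Y[c] = best;
        pY[c] = from;
      }
    }
  }

  const int end = n * w + m;
  double score = M[end];
  int state = 0;
  if (n == 0 || m == 0) {  // degenerate: pure gap alignment
    score = (n == 0 && m == 0) ? 0.0 : (n == 0 ? Y[end] : X[end]);
    state = (n == 0 && m == 0) ? 0 : (n == 0 ? 2 : 1);
  } else {
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }
  }

  std::vector<int> path;
  path.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM[i * w + j];
      path.push_back(0);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = pX[i * w + j];
      path.push_back(1);
      --i;
      state = prev;
    } else {
      int prev = pY[i * w + j];
      path.push_back(2);
      --j;
      state = prev;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
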