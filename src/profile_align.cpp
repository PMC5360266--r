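// Gotoh affine-gap global alignment over a precomputed column-pair score
// matrix. Used by the built-in progressive aligner to merge two profiles.
// Gap cost convention: a gap of length L costs gap_open + L * gap_ext.
// Deterministic tie-breaking: prefer match, then gap in B (consume A), then
// gap in A.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List affine_align_path(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state per cell and matrix: 0=M, 1=X, 2=Y, 3=start
  std::vector<unsigned char> tM((n + 1) * W, 3), tX((n + 1) * W, 3),
      tY((n + 1) * W, 3);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + i * gap_ext);
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + j * gap_ext);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // match state
      double best = M[d];
      unsigned char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      M[c] = best + C(i - 1, j - 1);
      tM[c] = tb;
      // gap in B: consume column i of A
      double open = M[u] - (gap_open + gap_ext);
      double ext = X[u] - gap_ext;
      double cross = Y[u] - (gap_open + gap_ext);
      if (open >= ext && open >= cross) { X[c] = open; tX[c] = 0; }
      else if (ext >= cross)            { X[c] = ext;  tX[c] = 1; }
      else                              { X[c] = cross; tX[c] = 2; }
      // gap in A: consume column j of B
      open = M[l] - (gap_open + gap_ext);
      ext = Y[l] - gap_ext;
      cross = X[l] - (gap_open + gap_ext);
      if (open >= ext && open >= cross) { Y[c] = open; tY[c] = 0; }
      else if (ext >= cross)            { Y[c] = ext;  tY[c] = 2; }
      else                              { Y[c] = cross; tY[c] = 1; }
    }
  }

  const int end = n * W + m;
  double best = M[end];
  unsigned char state = 0;
  if (X[end] > best) { best = X[end]; state = 1; }
  if (Y[end] > best) { best = Y[end]; state = 2; }

  // traceback: moves 0 = diagonal, 1 = consume A only, 2 = consume B only
  std::vector<int> rev;
  rev.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      rev.push_back(0);
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      rev.push_back(1);
      state = tX[c];
      --i;
    } else {
      rev.push_back(2);
      state = tY[c];
      --j;
    }
  }
  IntegerVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size() - 1 - k];
  return List::create(_["score"] = best, _["path"] = path);
}
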