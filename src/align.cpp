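#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh's three-state
// recursion.  A gap of length L costs gap_open + (L-1) * gap_ext.
// Tie-breaking is deterministic: diagonal (match state) is preferred over
// up (gap in b) over left (gap in a), both when choosing the final state
// and inside every max().
//
// a, b: 0-based integer encodings of the two sequences into the rows /
// columns of the substitution matrix `sub`.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  // state matrices: 0 = M (diagonal), 1 = X (up, gap in b), 2 = Y (left)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: previous state index for each cell/state
  std::vector<signed char> tM((n + 1) * (m + 1), -1);
  std::vector<signed char> tX((n + 1) * (m + 1), -1);
  std::vector<signed char> tY((n + 1) * (m + 1), -1);
  const int W = m + 1;

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_ext;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_ext;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, cd = (i - 1) * W + (j - 1),
                cu = (i - 1) * W + j, cl = i * W + (j - 1);
      // M: consume a[i-1] and b[j-1]
      {
        double best = M[cd]; signed char from = 0;
        if (X[cd] > best) { best = X[cd]; from = 1; }
        if (Y[cd] > best) { best = Y[cd]; from = 2; }
        if (best > NEG_INF / 2) {
          M[c] = best + sub(a[i - 1], b[j - 1]);
          tM[c] = from;
        }
      }
      // X: consume a[i-1] against a gap
      {
        double best = M[cu] + gap_open; signed char from = 0;
        if (X[cu] + gap_ext > best) { best = X[cu] + gap_ext; from = 1; }
        if (Y[cu] + gap_open > best) { best = Y[cu] + gap_open; from = 2; }
        X[c] = best; tX[c] = from;
      }
      // Y: consume b[j-1] against a gap
      {
        double best = M[cl] + gap_open; signed char from = 0;
        if (X[cl] + gap_open > best) { best = X[cl] + gap_open; from = 1; }
        if (Y[cl] + gap_ext > best) { best = Y[cl] + gap_ext; from = 2; }
        Y[c] = best; tY[c] = from;
      }
    }
  }

  const int end = n * W + m;
  int state = 0;
  double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::vector<int> outa, outb;  // -1 encodes a gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      outa.push_back(a[i - 1]); outb.push_back(b[j - 1]);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      outa.push_back(a[i - 1]); outb.push_back(-1);
      state = tX[c]; --i;
    } else {
      outa.push_back(-1); outb.push_back(b[j - 1]);
      state = tY[c]; --j;
    }
  }
  std::reverse(outa.begin(), outa.end());
  std::reverse(outb.begin(), outb.end());
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(outa.begin(), outa.end()),
                      _["b"] = IntegerVector(outb.begin(), outb.end()));
}
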