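#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed column-pair score
// matrix. States: M (align i with j), X (gap in the second profile: consumes
// row i), Y (gap in the first profile: consumes column j). gap_open is the
// score of the first gapped position, gap_extend of each further one.
// Deterministic tie-breaking: M > X > Y, both for the cell maxima and the
// traceback, so equal-scoring alignments resolve identically on every run.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".affine_align_path")]]
List affine_align_path(NumericMatrix score, double gap_open, double gap_extend) {
  const int n = score.nrow(), m = score.ncol();
  // DP matrices stored fully; traceback needs them. Memory: 3*(n+1)*(m+1)*8
  // bytes of double would be large at 6600x6600 (~1 GB), so scores are kept
  // in two rolling rows and the traceback in byte matrices.
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1));
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  Mprev[0] = 0.0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = (j == 1) ? gap_open : Yprev[j - 1] + gap_extend;
    tbY[idx(0, j)] = 2; // from Y (or start at j==1; traceback stops at 0,0)
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF;
    Ycur[0] = NEG_INF;
    Xcur[0] = (i == 1) ? gap_open : Xprev[0] + gap_extend;
    tbX[idx(i, 0)] = 1;
    for (int j = 1; j <= m; ++j) {
      // M: from diagonal, preference M > X > Y on ties
      double bM;
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      unsigned char fromM;
      if (dM >= dX && dM >= dY) { bM = dM; fromM = 0; }
      else if (dX >= dY)        { bM = dX; fromM = 1; }
      else                      { bM = dY; fromM = 2; }
      Mcur[j] = bM + score(i - 1, j - 1);
      tbM[idx(i, j)] = fromM;

      // X: consumes row i (gap in second profile); from up
      double oM = Mprev[j] + gap_open;
      double eX = Xprev[j] + gap_extend;
      double oY = Yprev[j] + gap_open;
      unsigned char fromX;
      double bX;
      if (oM >= eX && oM >= oY) { bX = oM; fromX = 0; }
      else if (eX >= oY)        { bX = eX; fromX = 1; }
      else                      { bX = oY; fromX = 2; }
      Xcur[j] = bX;
      tbX[idx(i, j)] = fromX;

      // Y: consumes column j (gap in first profile); from left
      double oM2 = Mcur[j - 1] + gap_open;
      double oX2 = Xcur[j - 1] + gap_open;
      double eY = Ycur[j - 1] + gap_extend;
      unsigned char fromY;
      double bY;
      if (oM2 >= oX2 && oM2 >= eY) { bY = oM2; fromY = 0; }
      else if (oX2 >= eY)          { bY = oX2; fromY = 1; }
      else                         { bY = eY; fromY = 2; }
      Ycur[j] = bY;
      tbY[idx(i, j)] = fromY;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  double endM = Mprev[m], endX = Xprev[m], endY = Yprev[m];
  unsigned char state;
  double best;
  if (endM >= endX && endM >= endY) { best = endM; state = 0; }
  else if (endX >= endY)            { best = endX; state = 1; }
  else                              { best = endY; state = 2; }

  std::vector<int> path;
  path.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    path.push_back(state);
    unsigned char prev;
    if (state == 0)      { prev = tbM[idx(i, j)]; --i; --j; }
    else if (state == 1) { prev = tbX[idx(i, j)]; --i; }
    else                 { prev = tbY[idx(i, j)]; --j; }
    state = prev;
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = best,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
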