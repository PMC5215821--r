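#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Fused profile-profile affine alignment: cell scores are computed on the
// fly from the residue content of each profile column (sum-of-pairs over
// non-gap residues divided by n1*n2), avoiding the L1 x L2 score matrix.
// Residues are integers 1..20, 0 for a gap. Tie-breaking and gap handling
// match affine_align_path (M > X > Y; X consumes profile-1 columns).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".affine_align_profiles")]]
List affine_align_profiles(IntegerMatrix resA, IntegerMatrix resB,
                           NumericMatrix S, double gap_open,
                           double gap_extend) {
  const int n = resA.ncol(), m = resB.ncol();
  const int ra = resA.nrow(), rb = resB.nrow();
  const double norm = 1.0 / (double(ra) * double(rb));

  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1));
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  // 21 x 21 lookup with gap row/column zero (index 0 = gap)
  std::vector<double> lut(21 * 21, 0.0);
  for (int a = 1; a <= 20; ++a)
    for (int b = 1; b <= 20; ++b)
      lut[a * 21 + b] = S(a - 1, b - 1);

  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF; Xprev[j] = NEG_INF;
    Yprev[j] = (j == 1) ? gap_open : Yprev[j - 1] + gap_extend;
    tbY[idx(0, j)] = 2;
  }

  std::vector<int> colA(ra);
  for (int i = 1; i <= n; ++i) {
    for (int r = 0; r < ra; ++r) colA[r] = resA(r, i - 1);
    Mcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    Xcur[0] = (i == 1) ? gap_open : Xprev[0] + gap_extend;
    tbX[idx(i, 0)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sc = 0.0;
      for (int r = 0; r < ra; ++r) {
        const int a = colA[r];
        if (a == 0) continue;
        const double* row = &lut[a * 21];
        for (int r2 = 0; r2 < rb; ++r2) sc += row[resB(r2, j - 1)];
      }
      sc *= norm;

      double bM; unsigned char fromM;
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      if (dM >= dX && dM >= dY) { bM = dM; fromM = 0; }
      else if (dX >= dY)        { bM = dX; fromM = 1; }
      else                      { bM = dY; fromM = 2; }
      Mcur[j] = bM + sc;
      tbM[idx(i, j)] = fromM;

      double oM = Mprev[j] + gap_open, eX = Xprev[j] + gap_extend,
             oY = Yprev[j] + gap_open;
      double bX; unsigned char fromX;
      if (oM >= eX && oM >= oY) { bX = oM; fromX = 0; }
      else if (eX >= oY)        { bX = eX; fromX = 1; }
      else                      { bX = oY; fromX = 2; }
      Xcur[j] = bX; tbX[idx(i, j)] = fromX;

      double oM2 = Mcur[j - 1] + gap_open, oX2 = Xcur[j - 1] + gap_open,
             eY = Ycur[j - 1] + gap_extend;
      double bY; unsigned char fromY;
      if (oM2 >= oX2 && oM2 >= eY) { bY = oM2; fromY = 0; }
      else if (oX2 >= eY)          { bY = oX2; fromY = 1; }
      else                         { bY = eY; fromY = 2; }
      Ycur[j] = bY; tbY[idx(i, j)] = fromY;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  double endM = Mprev[m], endX = Xprev[m], endY = Yprev[m];
  unsigned char state; double best;
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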