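#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Three-state pair-HMM forward dynamic programming for the TKF91 transducer,
// in linear space with per-row rescaling (exact up to floating point; avoids
// per-cell log-sum-exp). States: 0 = M (consumes one ancestor and one
// descendant position), 1 = D (ancestor only), 2 = I (descendant only). The
// caller supplies the 3x3 transition matrix (row = from, col = to; the start
// behaves like M), per-state end weights, the n x m match emission matrix
// and descendant insert emissions, all as probabilities. Delete emits
// nothing.

struct Fwd {
  std::vector<double> F;          // 3 * (n+1) * (m+1), state fastest
  std::vector<double> rowlog;     // cumulative log scale per row
  double logZ;
  int n, m;
};

static Fwd forward_lin(const NumericMatrix& match, const NumericVector& ins,
                       const NumericMatrix& trans, const NumericVector& end) {
  const int n = match.nrow(), m = match.ncol();
  Fwd r;
  r.n = n; r.m = m;
  r.F.assign((size_t)3 * (n + 1) * (m + 1), 0.0);
  r.rowlog.assign(n + 1, 0.0);
  auto F = [&](int s, int i, int j) -> double& {
    return r.F[((size_t)i * (m + 1) + j) * 3 + s];
  };
  const double tMM = trans(0, 0), tDM = trans(1, 0), tIM = trans(2, 0);
  const double tMD = trans(0, 1), tDD = trans(1, 1), tID = trans(2, 1);
  const double tMI = trans(0, 2), tDI = trans(1, 2), tII = trans(2, 2);

  // row 0: only I runs along j (start acts like M)
  double cum0 = 0.0;
  for (int j = 1; j <= m; ++j) {
    double prev = (j == 1) ? tMI : F(2, 0, j - 1) * tII;
    F(2, 0, j) = prev * ins[j - 1];
  }
  r.rowlog[0] = cum0;

  for (int i = 1; i <= n; ++i) {
    // scale factor between row i-1 and i is carried through rowlog; the
    // recurrences only mix rows i-1 and i, and row i-1 values are used as
    // stored (already scaled); we rescale row i after filling it.
    // D at j = 0
    F(1, i, 0) = (i == 1) ? tMD
                          : (F(0, i - 1, 0) * tMD + F(1, i - 1, 0) * tDD +
                             F(2, i - 1, 0) * tID);
    double rowmax = F(1, i, 0);
    for (int j = 1; j <= m; ++j) {
      double pM;
      if (i == 1 && j == 1) {
        pM = tMM;
      } else {
        pM = F(0, i - 1, j - 1) * tMM + F(1, i - 1, j - 1) * tDM +
             F(2, i - 1, j - 1) * tIM;
      }
      const double vM = pM * match(i - 1, j - 1);
      F(0, i, j) = vM;

      const double vD = F(0, i - 1, j) * tMD + F(1, i - 1, j) * tDD +
                        F(2, i - 1, j) * tID;
      F(1, i, j) = vD;

      double pI;
      if (i == 0 && j == 1) { // unreachable here (i >= 1); kept for clarity
        pI = tMI;
      } else {
        pI = F(0, i, j - 1) * tMI + F(1, i, j - 1) * tDI +
             F(2, i, j - 1) * tII;
      }
      const double vI = pI * ins[j - 1];
      F(2, i, j) = vI;

      if (vM > rowmax) rowmax = vM;
      if (vD > rowmax) rowmax = vD;
      if (vI > rowmax) rowmax = vI;
    }
    if (rowmax <= 0.0 || !std::isfinite(rowmax)) rowmax = 1.0;
    const double inv = 1.0 / rowmax;
    for (int j = 0; j <= m; ++j)
      for (int s = 0; s < 3; ++s) F(s, i, j) *= inv;
    r.rowlog[i] = r.rowlog[i - 1] + std::log(rowmax);
  }

  double z;
  if (n == 0 && m == 0) {
    r.logZ = std::log(end[0]);
  } else {
    z = F(0, n, m) * end[0] + F(1, n, m) * end[1] + F(2, n, m) * end[2];
    r.logZ = std::log(z) + r.rowlog[n];
  }
  return r;
}

// [[Rcpp::export(name = ".pairhmm_logZ")]]
double pairhmm_logZ(NumericMatrix match, NumericVector ins,
                    NumericMatrix trans, NumericVector end) {
  return forward_lin(match, ins, trans, end).logZ;
}

// Stochastic traceback: samples a path from the exact conditional
// distribution over alignments given both sequences. Uses R's RNG so seeds
// set in R govern reproducibility. Returns path codes (0 M, 1 D, 2 I), the
// forward log normalizer, and the log conditional probability of the
// sampled path. Within each traceback step all candidate predecessors live
// on one DP row, so row rescaling cancels out of the choice weights.
// [[Rcpp::export(name = ".pairhmm_sample")]]
List pairhmm_sample(NumericMatrix match, NumericVector ins,
                    NumericMatrix trans, NumericVector end) {
  Fwd r = forward_lin(match, ins, trans, end);
  const int n = r.n, m = r.m;
  auto F = [&](int s, int i, int j) -> double {
    return r.F[((size_t)i * (m + 1) + j) * 3 + s];
  };
  std::vector<int> rev;
  double logq = 0.0;
  int i = n, j = m, state = -1;
  if (!(n == 0 && m == 0)) {
    double w[3];
    for (int s = 0; s < 3; ++s) w[s] = F(s, n, m) * end[s];
    double tot = w[0] + w[1] + w[2];
    double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
    for (int s = 0; s < 3; ++s) {
      acc += w[s];
      if (u <= acc || s == 2) {
        state = s;
        logq += std::log(w[s] / tot);
        break;
      }
    }
    while (true) {
      rev.push_back(state);
      int pi_ = i, pj = j;
      if (state == 0) { pi_ = i - 1; pj = j - 1; }
      else if (state == 1) { pi_ = i - 1; }
      else { pj = j - 1; }
      if (pi_ == 0 && pj == 0) break;
      double wv[3];
      for (int s = 0; s < 3; ++s) wv[s] = F(s, pi_, pj) * trans(s, state);
      double tot2 = wv[0] + wv[1] + wv[2];
      int chosen = 2;
      if (tot2 > 0) {
        double u2 = R::runif(0.0, 1.0) * tot2, acc2 = 0.0;
        for (int s = 0; s < 3; ++s) {
          acc2 += wv[s];
          if (u2 <= acc2) { chosen = s; break; }
        }
      } else { // numeric degeneracy: take the best available state
        chosen = 0;
        for (int s = 1; s < 3; ++s) if (wv[s] > wv[chosen]) chosen = s;
      }
      logq += std::log(wv[chosen] / tot2);
      state = chosen;
      i = pi_; j = pj;
    }
    std::reverse(rev.begin(), rev.end());
  }
  return List::create(_["path"] = IntegerVector(rev.begin(), rev.end()),
                      _["logZ"] = r.logZ,
                      _["logq"] = logq);
}
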