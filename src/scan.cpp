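#include <Rcpp.h>
using namespace Rcpp;

// Ungapped diagonal triplex scan of a third-strand sequence A against a
// duplex strand P under a 4x4 triad weight matrix (rows: RNA base ACGU,
// cols: duplex scanned-strand base ACGT; code -1 = ambiguous, weight 0).
//
// On each diagonal, a window [s,e] qualifies iff
//   len >= lg, 100*nz >= idmin*len, sum_w >= smin*len.
// Overlapping qualifying windows on one diagonal form a component; the
// reported segment per component is the stability-maximal qualifying window
// (ties: longest, then leftmost). Early termination uses suffix max-gain
// bounds, which is exact: scanning for a start stops only when no position
// further right can satisfy a constraint again.
//
// Coordinates returned are 1-based indices into A (a1, a2) and P (p1, p2).

static inline bool better_window(double sw_c, int len_c, double sw_b, int len_b) {
  // higher mean stability first (cross-multiplied), then longer
  double lhs = sw_c * (double)len_b;
  double rhs = sw_b * (double)len_c;
  if (lhs > rhs + 1e-9) return true;
  if (std::fabs(lhs - rhs) <= 1e-9 && len_c > len_b) return true;
  return false;
}

// [[Rcpp::export]]
DataFrame scan_pair_cpp(IntegerVector a_codes, IntegerVector p_codes,
                        NumericMatrix wm, int lg, double idmin, double smin) {
  const int m = a_codes.size(), n = p_codes.size();
  const double EPS = 1e-9;

  std::vector<int> out_a1, out_a2, out_p1, out_p2, out_nz;
  std::vector<double> out_sw;

  // weight lookup with code -1 (ambiguous) folded in as row/col 0 of a 5x5
  double wtab[5][5];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      wtab[a][b] = (a == 0 || b == 0) ? 0.0 : wm(a - 1, b - 1);
  std::vector<int> ac(m), pc(n);
  for (int i = 0; i < m; ++i) ac[i] = a_codes[i] + 1;
  for (int i = 0; i < n; ++i) pc[i] = p_codes[i] + 1;

  std::vector<double> w(std::min(m, n)), x1(std::min(m, n)),
      x2(std::min(m, n)), M1(std::min(m, n)), M2(std::min(m, n));

  for (int d = -(m - 1); d <= n - 1; ++d) {
    int aLo = std::max(0, -d);
    int aHi = std::min(m - 1, n - 1 - d);
    int Lw = aHi - aLo + 1;
    if (Lw < lg) continue;

    bool any_nz = false;
    for (int t = 0; t < Lw; ++t) {
      double wt = wtab[ac[aLo + t]][pc[aLo + t + d]];
      w[t] = wt;
      x1[t] = (wt > 0 ? 100.0 : 0.0) - idmin;
      x2[t] = wt - smin;
      if (wt > 0) any_nz = true;
    }
    if (!any_nz) continue;
    // M[t] = max over u in (t, Lw-1] of sum_{v=t+1}^{u} x[v]; -inf at t=Lw-1
    M1[Lw - 1] = -1e300;
    M2[Lw - 1] = -1e300;
    for (int t = Lw - 2; t >= 0; --t) {
      M1[t] = x1[t + 1] + std::max(0.0, M1[t + 1]);
      M2[t] = x2[t + 1] + std::max(0.0, M2[t + 1]);
    }

    bool compActive = false;
    int compEnd = -1;           // max union end of current component
    double bSw = 0.0; int bLen = 0, bS = -1, bE = -1, bNz = 0;

    for (int s = 0; s + lg <= Lw; ++s) {
      double D1 = 0.0, D2 = 0.0, sw = 0.0;
      int nz = 0;
      int emax = -1;
      double sBestSw = 0.0; int sBestLen = 0, sBestE = -1, sBestNz = 0;
      for (int e = s; e < Lw; ++e) {
        D1 += x1[e];
        D2 += x2[e];
        sw += w[e];
        if (w[e] > 0) ++nz;
        int len = e - s + 1;
        if (len >= lg && D1 >= -EPS && D2 >= -EPS) {
          emax = e;
          if (sBestE < 0 || better_window(sw, len, sBestSw, sBestLen)) {
            sBestSw = sw; sBestLen = len; sBestE = e; sBestNz = nz;
          }
        }
        if (e == Lw - 1) break;
        if (D1 + M1[e] < -EPS) break;
        if (D2 + M2[e] < -EPS) break;
      }
      if (emax < 0) continue;

      if (compActive && s <= compEnd) {
        if (emax > compEnd) compEnd = emax;
        if (better_window(sBestSw, sBestLen, bSw, bLen)) {
          bSw = sBestSw; bLen = sBestLen; bS = s; bE = sBestE; bNz = sBestNz;
        }
      } else {
        if (compActive) {
          out_a1.push_back(aLo + bS + 1);
          out_a2.push_back(aLo + bE + 1);
          out_p1.push_back(aLo + bS + d + 1);
          out_p2.push_back(aLo + bE + d + 1);
          out_nz.push_back(bNz);
          out_sw.push_back(bSw);
        }
        compActive = true;
        compEnd = emax;
        bSw = sBestSw; bLen = sBestLen; bS = s; bE = sBestE; bNz = sBestNz;
      }
    }
    if (compActive) {
      out_a1.push_back(aLo + bS + 1);
      out_a2.push_back(aLo + bE + 1);
      out_p1.push_back(aLo + bS + d + 1);
      out_p2.push_back(aLo + bE + d + 1);
      out_nz.push_back(bNz);
      out_sw.push_back(bSw);
    }
  }

  return DataFrame::create(
    _["a1"] = out_a1, _["a2"] = out_a2,
    _["p1"] = out_p1, _["p2"] = out_p2,
    _["nz"] = out_nz, _["sw"] = out_sw);
}
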