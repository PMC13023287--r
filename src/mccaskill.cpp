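#include <Rcpp.h>
using namespace Rcpp;

// McCaskill-style inside-outside computation of base-pairing probabilities
// for pseudoknot-free structures under a simple additive pair-energy model:
// a structure's Boltzmann weight is the product of exp(-E(pair)/kT) over its
// pairs. Pairs (i,j) are admissible iff q(i,j) > 0, j - i > min_hairpin and
// j - i <= max_span. Lone pairs are allowed; dangles are ignored.
//
// The inside recursion is the unambiguous decomposition on the rightmost
// position j of [i,j]:
//   Z(i,j) = Z(i,j-1) + sum_k Z(i,k-1) q(k,j) Z(k+1,j-1)
// and the outside pass propagates context weights of every span so that
//   P(k,j) = [sum_{i<=k} O(i,j) Z(i,k-1)] q(k,j) Z(k+1,j-1) / Z(1,n).
// Per-position rescaling (factor s per base) keeps magnitudes in range for
// windows of a few hundred nt; the scale cancels exactly in P.

struct McState {
  int n;
  double inv_s, inv_s2;
  std::vector<double> Z, O;   // (n x n), row-major, j < i means empty (== 1 for Z)
  inline double zin(int i, int j) const { return (j < i) ? 1.0 : Z[i * n + j]; }
};

// [[Rcpp::export]]
List mccaskill_window_cpp(IntegerVector codes, NumericMatrix qmat,
                          int min_hairpin, int max_span) {
  const int n = codes.size();
  NumericMatrix P(n, n);
  NumericVector punp(n);
  if (n == 0) return List::create(_["p"] = P, _["punp"] = punp);

  double qmax = 1.0;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) qmax = std::max(qmax, qmat(a, b));
  const double s = std::max(1.0, std::pow(qmax, 0.25));

  McState st;
  st.n = n;
  st.inv_s = 1.0 / s;
  st.inv_s2 = 1.0 / (s * s);
  st.Z.assign((size_t)n * n, 0.0);
  st.O.assign((size_t)n * n, 0.0);

  std::vector<double> q((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + min_hairpin + 1; j < n && j - i <= max_span; ++j) {
      int ci = codes[i], cj = codes[j];
      if (ci >= 0 && cj >= 0) q[(size_t)i * n + j] = qmat(ci, cj);
    }

  // inside
  for (int j = 0; j < n; ++j) {
    for (int i = j; i >= 0; --i) {
      double z = st.zin(i, j - 1) * st.inv_s;  // j unpaired
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        double qk = q[(size_t)k * n + j];
        if (qk > 0.0)
          z += st.zin(i, k - 1) * qk * st.inv_s2 * st.zin(k + 1, j - 1);
      }
      st.Z[(size_t)i * n + j] = z;
    }
  }
  const double Ztot = st.zin(0, n - 1);

  // outside, spans from longest to shortest
  st.O[(size_t)0 * n + (n - 1)] = 1.0;
  for (int len = n - 1; len >= 1; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (i == 0 && j == n - 1) continue;
      double o = 0.0;
      if (j + 1 < n) {
        // parent [i, j+1] with j+1 unpaired
        o += st.O[(size_t)i * n + (j + 1)] * st.inv_s;
        // parent [i, l] with pair (j+1, l)
        for (int l = j + 2; l < n; ++l) {
          double ql = q[(size_t)(j + 1) * n + l];
          if (ql > 0.0)
            o += st.O[(size_t)i * n + l] * ql * st.inv_s2 * st.zin(j + 2, l - 1);
        }
        // inner part of pair (i-1, j+1) inside parents [i', j+1]
        if (i >= 1) {
          double qp = q[(size_t)(i - 1) * n + (j + 1)];
          if (qp > 0.0) {
            double acc = 0.0;
            for (int ip = 0; ip <= i - 1; ++ip)
              acc += st.O[(size_t)ip * n + (j + 1)] * st.zin(ip, i - 2);
            o += acc * qp * st.inv_s2;
          }
        }
      }
      st.O[(size_t)i * n + j] = o;
    }
  }

  // pair probabilities and unpaired profile
  std::vector<double> psum(n, 0.0);
  for (int k = 0; k < n; ++k) {
    for (int j = k + min_hairpin + 1; j < n; ++j) {
      double qk = q[(size_t)k * n + j];
      if (qk <= 0.0) continue;
      double acc = 0.0;
      for (int i = 0; i <= k; ++i)
        acc += st.O[(size_t)i * n + j] * st.zin(i, k - 1);
      double p = acc * qk * st.inv_s2 * st.zin(k + 1, j - 1) / Ztot;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      P(k, j) = p;
      P(j, k) = p;
      psum[k] += p;
      psum[j] += p;
    }
  }
  for (int i = 0; i < n; ++i) {
    double u = 1.0 - psum[i];
    punp[i] = std::min(1.0, std::max(0.0, u));
  }
  return List::create(_["p"] = P, _["punp"] = punp);
}

// Windowed unpaired-probability profile: windows of length min(W, n) slide
// with step 1; the profile at a position is the arithmetic mean of its
// per-window unpaired probabilities over every window containing it.
// [[Rcpp::export]]
NumericVector punp_profile_cpp(IntegerVector codes, NumericMatrix qmat,
                               int min_hairpin, int max_span, int W) {
  const int n = codes.size();
  NumericVector prof(n);
  if (n == 0) return prof;
  const int w = std::min(W, n);
  std::vector<double> sums(n, 0.0);
  std::vector<int> cnts(n, 0);
  for (int t = 0; t + w <= n; ++t) {
    IntegerVector sub(codes.begin() + t, codes.begin() + t + w);
    List res = mccaskill_window_cpp(sub, qmat, min_hairpin, max_span);
    NumericVector pu = res["punp"];
    for (int i = 0; i < w; ++i) {
      sums[t + i] += pu[i];
      cnts[t + i] += 1;
    }
  }
  for (int i = 0; i < n; ++i) prof[i] = sums[i] / cnts[i];
  return prof;
}
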