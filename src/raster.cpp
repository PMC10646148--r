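#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Low-level raster primitives shared by the masking and skeleton stages.
// All neighborhood operations use 8-connectivity, matching the diagonal
// continuity of 1-px-wide neurite centerlines.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8-connected component labeling by iterative flood fill (BFS).
// Returns an integer matrix: 0 = background, 1..k = component id.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = cr + DR[k], cch = cc + DC[k];
          if (rr < 0 || rr >= nr || cch < 0 || cch >= nc) continue;
          if (mask(rr, cch) && !lab(rr, cch)) {
            lab(rr, cch) = next;
            stack.push_back(rr + cch * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Count of TRUE 8-neighbors for every pixel (borders treated as FALSE).
// [[Rcpp::export(name = ".neighbor_count8")]]
IntegerMatrix neighbor_count8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int n = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc)) ++n;
      }
      out(r, c) = n;
    }
  }
  return out;
}

// Helpers for the thinning conditions.  Neighborhood indexed in the
// Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW.
static inline void nbhd(const LogicalMatrix& m, int r, int c, int p[8]) {
  const int nr = m.nrow(), nc = m.ncol();
  static const int zr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int zc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int k = 0; k < 8; ++k) {
    int rr = r + zr[k], cc = c + zc[k];
    p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc)) ? 1 : 0;
  }
}

static inline int transitions01(const int p[8]) {
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
  return a;
}

// Guo-Hall connectivity number: number of foreground runs in the ring,
// evaluated with the 4-term crossing formula. p[] in Zhang-Suen order
// P2..P9 = N, NE, E, SE, S, SW, W, NW.
static inline int gh_C(const int p[8]) {
  return ((!p[0]) & (p[1] | p[2])) + ((!p[2]) & (p[3] | p[4])) +
         ((!p[4]) & (p[5] | p[6])) + ((!p[6]) & (p[7] | p[0]));
}

static inline int gh_N(const int p[8]) {
  int n1 = (p[7] | p[0]) + (p[1] | p[2]) + (p[3] | p[4]) + (p[5] | p[6]);
  int n2 = (p[0] | p[1]) + (p[2] | p[3]) + (p[4] | p[5]) + (p[6] | p[7]);
  return n1 < n2 ? n1 : n2;
}

// Topology-preserving thinning of the Zhang-Suen family.  Candidate pixels
// are selected with the classical two directional sub-iterations; deletions
// within a sub-iteration are applied sequentially in column-major scan
// order, re-checking the connectivity condition (A == 1, 2 <= B <= 6)
// against the current image before each removal.  The sequential re-check
// makes every deletion a simple-point deletion, so 8-connected component
// topology is preserved exactly (the parallel variant can delete an
// isolated 2x2 block outright).  Iterates to a fixed point, hence the
// operator is idempotent.
// [[Rcpp::export(name = ".thin_skeleton")]]
LogicalMatrix thin_skeleton(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  bool changed = true;
  int p[8];
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      // candidate selection against the sub-iteration snapshot (parallel
      // Zhang-Suen conditions)
      cand.clear();
      LogicalMatrix snap = clone(img);
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!snap(r, c)) continue;
          nbhd(snap, r, c, p);
          if (gh_C(p) != 1) continue;
          int n = gh_N(p);
          if (n < 2 || n > 3) continue;
          // directional masks of the two sub-iterations
          int m = (phase == 0) ? ((p[4] | p[5] | !p[7]) & p[6])
                               : ((p[0] | p[1] | !p[3]) & p[2]);
          if (m) continue;
          cand.push_back(r + c * nr);
        }
      }
      // sequential deletion with a connectivity re-check against the
      // current image: each removal is then a simple-point deletion, so
      // 8-connected topology is preserved even where the parallel rule
      // would delete an isolated small block outright
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i] % nr, c = cand[i] / nr;
        nbhd(img, r, c, p);
        if (gh_C(p) != 1) continue;        // would split or vanish a part
        int b = 0;
        for (int k = 0; k < 8; ++k) b += p[k];
        if (b < 2) continue;               // endpoint: would shorten
        img(r, c) = false;
        changed = true;
      }
    }
  }
  return img;
}

// Separable convolution with reflective (mirror-without-repeat) boundary
// handling: row kernel `ky` applied down columns, then column kernel `kx`
// along rows.  Kernels must have odd length.
// [[Rcpp::export(name = ".sep_convolve")]]
NumericMatrix sep_convolve(const NumericMatrix& img,
                           const NumericVector& ky,
                           const NumericVector& kx) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hy = ky.size() / 2, hx = kx.size() / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hy; k <= hy; ++k) {
        int rr = r + k;
        if (rr < 0) rr = -rr;                 // reflect about pixel 0
        if (rr >= nr) rr = 2 * nr - 2 - rr;   // reflect about pixel nr-1
        if (rr < 0) rr = 0;                   // degenerate tiny images
        if (rr >= nr) rr = nr - 1;
        s += ky[k + hy] * img(rr, c);
      }
      tmp(r, c) = s;
    }
  }
  // horizontal pass
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hx; k <= hx; ++k) {
        int cc = c + k;
        if (cc < 0) cc = -cc;
        if (cc >= nc) cc = 2 * nc - 2 - cc;
        if (cc < 0) cc = 0;
        if (cc >= nc) cc = nc - 1;
        s += kx[k + hx] * tmp(r, cc);
      }
      out(r, c) = s;
    }
  }
  return out;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance from every pixel to the nearest TRUE pixel of `mask`.
// Returns +Inf where the mask is empty.
// Lower-envelope scan over the finite entries of f only; entries equal to
// +Inf contribute no parabola.  If no entry is finite, d is all +Inf.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;  // never below 0: z[0] = -Inf
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    d[q] = (q - v[j]) * (double)(q - v[j]) + f[v[j]];
  }
}

// [[Rcpp::export(name = ".distance_to_mask")]]
NumericMatrix distance_to_mask(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix g(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      g(r, c) = mask(r, c) ? 0.0 : INF;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // along columns
  for (int c = 0; c < nc; ++c) {
    bool any = false;
    for (int r = 0; r < nr; ++r) { f[r] = g(r, c); if (f[r] == 0.0) any = true; }
    if (!any) continue;  // stays +Inf, merged in row pass
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  // along rows
  for (int r = 0; r < nr; ++r) {
    bool finite = false;
    for (int c = 0; c < nc; ++c) { f[c] = g(r, c); if (f[c] < INF) finite = true; }
    if (!finite) continue;
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = d[c];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (g(r, c) < INF) g(r, c) = std::sqrt(g(r, c));
  return g;
}

// Huang & Wang minimum-fuzziness threshold, evaluated exhaustively over all
// occupied gray levels.  `levels` are the distinct gray values present,
// `counts` their pixel counts.  Membership of gray g to its class with mean
// mu is 1 / (1 + |g - mu| / C) with C the occupied gray-level range; the
// fuzziness of a candidate threshold is the Shannon entropy of memberships,
// summed over the histogram.  Returns the level minimizing the entropy
// (ties -> lowest level); foreground is "strictly above threshold".
// [[Rcpp::export(name = ".huang_scan")]]
List huang_scan(const NumericVector& levels, const NumericVector& counts) {
  const int n = levels.size();
  const double C = levels[n - 1] - levels[0];
  std::vector<double> cw(n), cwx(n);  // cumulative count, count*level
  double w = 0, wx = 0;
  for (int i = 0; i < n; ++i) {
    w += counts[i];
    wx += counts[i] * levels[i];
    cw[i] = w; cwx[i] = wx;
  }
  const double W = cw[n - 1], WX = cwx[n - 1];
  double best = std::numeric_limits<double>::infinity();
  int besti = 0;
  NumericVector ent(n - 1);
  for (int t = 0; t < n - 1; ++t) {       // threshold = levels[t]; fg > it
    double mu0 = cwx[t] / cw[t];
    double mu1 = (WX - cwx[t]) / (W - cw[t]);
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      double mu = 1.0 / (1.0 + std::fabs(levels[i] - (i <= t ? mu0 : mu1)) / C);
      if (mu > 0.0 && mu < 1.0)
        e += counts[i] * (-mu * std::log(mu) - (1.0 - mu) * std::log(1.0 - mu));
    }
    ent[t] = e;
    if (e < best) { best = e; besti = t; }
  }
  return List::create(_["threshold"] = levels[besti], _["entropy"] = ent);
}
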