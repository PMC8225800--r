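#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Low-level raster primitives used by the segmentation stage. Images are
// numeric/integer matrices in R's column-major layout; (r, c) are 0-based here.

// 8-connected component labelling by flood fill. Labels are assigned in
// raster-scan order of the first pixel encountered, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc2 = p.second + dc;
            if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
            if (mask(rr, cc2) && lab(rr, cc2) == 0) {
              lab(rr, cc2) = next;
              stack.push_back(std::make_pair(rr, cc2));
            }
          }
        }
      }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean squared distance to the nearest background (FALSE) pixel.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e15;
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass along rows (within each column)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // pass along columns (within each row)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}

struct WsNode {
  double elev;
  long order;
  int r, c, label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Seeded watershed: flood `elev` upward from labelled seeds, restricted to
// `mask`. 4-connectivity during flooding keeps basin boundaries thin.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(const NumericMatrix& elev, const IntegerMatrix& seeds,
                            const LogicalMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        WsNode n = {elev(r, c), order++, r, c, seeds(r, c)};
        pq.push(n);
      }
  const int DR[4] = {-1, 1, 0, 0};
  const int DC[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = n.r + DR[k], cc2 = n.c + DC[k];
      if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
      if (!mask(rr, cc2) || lab(rr, cc2) != 0) continue;
      lab(rr, cc2) = n.label;
      WsNode m = {elev(rr, cc2), order++, rr, cc2, n.label};
      pq.push(m);
    }
  }
  return lab;
}

// Square maximum filter of half-width `radius` (used for peak detection).
// [[Rcpp::export]]
NumericMatrix maxfilter_cpp(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int d = -radius; d <= radius; ++d) {
        int rr = r + d;
        if (rr >= 0 && rr < nr && img(rr, c) > m) m = img(rr, c);
      }
      tmp(r, c) = m;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int d = -radius; d <= radius; ++d) {
        int cc2 = c + d;
        if (cc2 >= 0 && cc2 < nc && tmp(r, cc2) > m) m = tmp(r, cc2);
      }
      out(r, c) = m;
    }
  return out;
}
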