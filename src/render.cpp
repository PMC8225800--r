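#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place rendering primitives for the synthetic-stack generator. All three
// mutate `img` directly (NumericMatrix wraps the caller's memory); the R
// layer owns a fresh buffer per channel, so no user-visible object aliases it.

// [[Rcpp::export]]
void stamp_gauss_ip(NumericMatrix img, double r0, double c0, double sigma,
                    double amp) {
  const int nr = img.nrow(), nc = img.ncol();
  const int w = (int)std::ceil(4.0 * sigma);
  if (r0 + w < 1 || r0 - w > nr || c0 + w < 1 || c0 - w > nc) return;
  const int rlo = std::max(1, (int)std::floor(r0 - w));
  const int rhi = std::min(nr, (int)std::ceil(r0 + w));
  const int clo = std::max(1, (int)std::floor(c0 - w));
  const int chi = std::min(nc, (int)std::ceil(c0 + w));
  const double s2 = 2.0 * sigma * sigma;
  for (int c = clo; c <= chi; ++c) {
    const double gc = std::exp(-(c - c0) * (c - c0) / s2);
    for (int r = rlo; r <= rhi; ++r) {
      const double gr = std::exp(-(r - r0) * (r - r0) / s2);
      img(r - 1, c - 1) += amp * gr * gc;
    }
  }
}

// flat-topped soma profile (super-Gaussian of order 4)
// [[Rcpp::export]]
void stamp_soma_ip(NumericMatrix img, double r0, double c0, double radius,
                   double amp) {
  const int nr = img.nrow(), nc = img.ncol();
  const int w = (int)std::ceil(2.0 * radius);
  if (r0 + w < 1 || r0 - w > nr || c0 + w < 1 || c0 - w > nc) return;
  const int rlo = std::max(1, (int)std::floor(r0 - w));
  const int rhi = std::min(nr, (int)std::ceil(r0 + w));
  const int clo = std::max(1, (int)std::floor(c0 - w));
  const int chi = std::min(nc, (int)std::ceil(c0 + w));
  const double rad2 = radius * radius;
  for (int c = clo; c <= chi; ++c)
    for (int r = rlo; r <= rhi; ++r) {
      const double d2 = (r - r0) * (r - r0) + (c - c0) * (c - c0);
      const double u = d2 / rad2;
      img(r - 1, c - 1) += amp * std::exp(-0.5 * u * u);
    }
}

// ridge along a polyline (n x 2 matrix of (row, col) points): small
// Gaussians at `step`-spaced samples, normalized so the crest is ~`amp`
// [[Rcpp::export]]
void stamp_polyline_ip(NumericMatrix img, NumericMatrix pts, double sigma,
                       double amp) {
  const double step = 0.75;
  const double amp_eff = amp * step / (std::sqrt(2.0 * M_PI) * sigma);
  for (int s = 0; s + 1 < pts.nrow(); ++s) {
    const double pr = pts(s, 0), pc = pts(s, 1);
    const double qr = pts(s + 1, 0), qc = pts(s + 1, 1);
    const double L = std::sqrt((qr - pr) * (qr - pr) + (qc - pc) * (qc - pc));
    if (L <= 0) continue;
    const int nstep = (int)std::floor(L / step);
    for (int k = 0; k <= nstep; ++k) {
      const double t = (k * step) / L;
      stamp_gauss_ip(img, pr + t * (qr - pr), pc + t * (qc - pc), sigma,
                     amp_eff);
    }
  }
}
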