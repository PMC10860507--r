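#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// 3-D gamma-index search. Reference voxels are compared against the
// evaluated field interpolated trilinearly on a subsampled offset lattice
// inside a bounded search radius; offsets are visited in order of
// increasing spatial distance so the search stops as soon as the distance
// term alone exceeds the best gamma found.

struct Offset { double d1, d2, d3, dist2; };

static double lerp3(const double *vol, int n1, int n2, int n3,
                    double x1, double x2, double x3, bool &inside) {
  if (x1 < 0 || x2 < 0 || x3 < 0 ||
      x1 > n1 - 1 || x2 > n2 - 1 || x3 > n3 - 1) { inside = false; return 0.0; }
  inside = true;
  int i1 = std::min((int)std::floor(x1), n1 - 2);
  int i2 = std::min((int)std::floor(x2), n2 - 2);
  int i3 = std::min((int)std::floor(x3), n3 - 2);
  if (i1 < 0) i1 = 0;
  if (i2 < 0) i2 = 0;
  if (i3 < 0) i3 = 0;
  int j1 = (n1 > 1) ? 1 : 0, j2 = (n2 > 1) ? 1 : 0, j3 = (n3 > 1) ? 1 : 0;
  double t1 = x1 - i1, t2 = x2 - i2, t3 = x3 - i3;
  R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  R_xlen_t b = (R_xlen_t)i1 + s2 * i2 + s3 * i3;
  double c00 = vol[b] * (1 - t1) + vol[b + j1] * t1;
  double c10 = vol[b + j2 * s2] * (1 - t1) + vol[b + j1 + j2 * s2] * t1;
  double c01 = vol[b + j3 * s3] * (1 - t1) + vol[b + j1 + j3 * s3] * t1;
  double c11 = vol[b + j2 * s2 + j3 * s3] * (1 - t1) + vol[b + j1 + j2 * s2 + j3 * s3] * t1;
  double c0 = c00 * (1 - t2) + c10 * t2;
  double c1 = c01 * (1 - t2) + c11 * t2;
  return c0 * (1 - t3) + c1 * t3;
}

// [[Rcpp::export(name = ".gamma_search_cpp")]]
NumericVector gamma_search_cpp(NumericVector refv, NumericVector evalv,
                               IntegerVector dim, NumericVector spacing,
                               double dd_frac, double dta_mm, double norm,
                               bool local_norm, double threshold_abs,
                               double radius_mm, int subsample) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double *rp = REAL(refv);
  const double *ep = REAL(evalv);

  // candidate offsets in mm, sorted by spatial distance
  std::vector<Offset> offs;
  double step[3] = { spacing[0] / subsample, spacing[1] / subsample,
                     spacing[2] / subsample };
  int K[3];
  for (int a = 0; a < 3; ++a) K[a] = (int)std::ceil(radius_mm / step[a]);
  double r2 = radius_mm * radius_mm;
  for (int k3 = -K[2]; k3 <= K[2]; ++k3)
    for (int k2 = -K[1]; k2 <= K[1]; ++k2)
      for (int k1 = -K[0]; k1 <= K[0]; ++k1) {
        Offset o;
        o.d1 = k1 * step[0]; o.d2 = k2 * step[1]; o.d3 = k3 * step[2];
        o.dist2 = o.d1 * o.d1 + o.d2 * o.d2 + o.d3 * o.d3;
        if (o.dist2 <= r2 + 1e-12) offs.push_back(o);
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.dist2 < b.dist2; });

  const double dta2 = dta_mm * dta_mm;
  NumericVector out(n);
  R_xlen_t v = 0;
  for (int x3 = 0; x3 < n3; ++x3)
    for (int x2 = 0; x2 < n2; ++x2)
      for (int x1 = 0; x1 < n1; ++x1, ++v) {
        double rd = rp[v];
        if (rd < threshold_abs) { out[v] = NA_REAL; continue; }
        double denom = dd_frac * (local_norm ? rd : norm);
        double denom2 = denom * denom;
        double best = std::numeric_limits<double>::infinity();
        for (size_t i = 0; i < offs.size(); ++i) {
          double dterm = offs[i].dist2 / dta2;
          if (dterm >= best) break;  // offsets sorted: no later one can win
          bool inside;
          double ev = lerp3(ep, n1, n2, n3,
                            x1 + offs[i].d1 / spacing[0],
                            x2 + offs[i].d2 / spacing[1],
                            x3 + offs[i].d3 / spacing[2], inside);
          if (!inside) continue;
          double dd = rd - ev;
          double g2 = dd * dd / denom2 + dterm;
          if (g2 < best) best = g2;
        }
        out[v] = std::sqrt(best);
      }
  return out;
}

// Naive exhaustive gamma used as an independent numerical oracle in tests:
// no sorting, no pruning, its own interpolation; visits every lattice
// offset in the bounding box and keeps the minimum.
// [[Rcpp::export(name = ".gamma_brute_cpp")]]
NumericVector gamma_brute_cpp(NumericVector refv, NumericVector evalv,
                              IntegerVector dim, NumericVector spacing,
                              double dd_frac, double dta_mm, double norm,
                              bool local_norm, double threshold_abs,
                              double radius_mm, int subsample) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double *rp = REAL(refv);
  const double *ep = REAL(evalv);
  double step[3] = { spacing[0] / subsample, spacing[1] / subsample,
                     spacing[2] / subsample };
  int K[3];
  for (int a = 0; a < 3; ++a) K[a] = (int)std::ceil(radius_mm / step[a]);
  const double r2 = radius_mm * radius_mm;
  const double dta2 = dta_mm * dta_mm;
  NumericVector out(n);
  R_xlen_t v = 0;
  for (int x3 = 0; x3 < n3; ++x3)
    for (int x2 = 0; x2 < n2; ++x2)
      for (int x1 = 0; x1 < n1; ++x1, ++v) {
        double rd = rp[v];
        if (rd < threshold_abs) { out[v] = NA_REAL; continue; }
        double denom = dd_frac * (local_norm ? rd : norm);
        double best = std::numeric_limits<double>::infinity();
        for (int k3 = -K[2]; k3 <= K[2]; ++k3)
          for (int k2 = -K[1]; k2 <= K[1]; ++k2)
            for (int k1 = -K[0]; k1 <= K[0]; ++k1) {
              double d1 = k1 * step[0], d2 = k2 * step[1], d3 = k3 * step[2];
              double dist2 = d1 * d1 + d2 * d2 + d3 * d3;
              if (dist2 > r2 + 1e-12) continue;
              double p1 = x1 + d1 / spacing[0];
              double p2 = x2 + d2 / spacing[1];
              double p3 = x3 + d3 / spacing[2];
              if (p1 < 0 || p2 < 0 || p3 < 0 ||
                  p1 > n1 - 1 || p2 > n2 - 1 || p3 > n3 - 1) continue;
              int i1 = std::min((int)std::floor(p1), std::max(n1 - 2, 0));
              int i2 = std::min((int)std::floor(p2), std::max(n2 - 2, 0));
              int i3 = std::min((int)std::floor(p3), std::max(n3 - 2, 0));
              double t1 = p1 - i1, t2 = p2 - i2, t3 = p3 - i3;
              int j1 = (n1 > 1) ? 1 : 0, j2 = (n2 > 1) ? 1 : 0, j3 = (n3 > 1) ? 1 : 0;
              R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
              R_xlen_t b = (R_xlen_t)i1 + s2 * i2 + s3 * i3;
              double ev =
                ((ep[b] * (1 - t1) + ep[b + j1] * t1) * (1 - t2) +
                 (ep[b + j2 * s2] * (1 - t1) + ep[b + j1 + j2 * s2] * t1) * t2) * (1 - t3) +
                ((ep[b + j3 * s3] * (1 - t1) + ep[b + j1 + j3 * s3] * t1) * (1 - t2) +
                 (ep[b + j2 * s2 + j3 * s3] * (1 - t1) +
                  ep[b + j1 + j2 * s2 + j3 * s3] * t1) * t2) * t3;
              double dd = rd - ev;
              double g2 = dd * dd / (denom * denom) + dist2 / dta2;
              if (g2 < best) best = g2;
            }
        out[v] = std::sqrt(best);
      }
  return out;
}
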