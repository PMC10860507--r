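#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact anisotropic Euclidean distance/feature transform
// (separable lower-envelope-of-parabolas method, one pass per axis,
// nearest-site index propagated so callers can recover box distances).

static const double INF = std::numeric_limits<double>::infinity();

// 1-D transform along one line. f: squared distances at n positions with
// inter-position spacing s (mm); site: nearest-site linear index per position.
// Overwrites f and site with the line-wise envelope minimum.
static void dt_line(std::vector<double> &f, std::vector<int> &site,
                    int n, double s) {
  std::vector<int> v(n);       // positions of parabolas in the envelope
  std::vector<double> z(n + 1);  // envelope breakpoints (in mm coordinates)
  std::vector<double> fout(n);
  std::vector<int> sout(n);
  int k = -1;
  const double s2 = s * s;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double qs = q * s;
    while (k >= 0) {
      int p = v[k];
      double ps = p * s;
      double x = ((f[q] + qs * qs) - (f[p] + ps * ps)) / (2.0 * (qs - ps));
      if (x <= z[k]) { --k; } else { break; }
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      int p = v[k];
      double ps = p * s;
      double x = ((f[q] + qs * qs) - (f[p] + ps * ps)) / (2.0 * (qs - ps));
      ++k; v[k] = q; z[k] = x; z[k + 1] = INF;
    }
  }
  if (k < 0) {  // no finite parabola on this line
    for (int q = 0; q < n; ++q) { fout[q] = INF; sout[q] = -1; }
  } else {
    int j = 0;
    for (int q = 0; q < n; ++q) {
      double xs = q * s;
      while (z[j + 1] < xs) ++j;
      int p = v[j];
      double d = xs - p * s;
      fout[q] = f[p] + d * d;
      sout[q] = site[p];
    }
  }
  f.swap(fout);
  site.swap(sout);
}

// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> D(n);
  std::vector<int> S(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) { D[i] = 0.0; S[i] = (int)i; }
    else { D[i] = INF; S[i] = -1; }
  }
  const int nn[3] = { n1, n2, n3 };
  const R_xlen_t stride[3] = { 1, (R_xlen_t)n1, (R_xlen_t)n1 * n2 };
  for (int ax = 0; ax < 3; ++ax) {
    const int len = nn[ax];
    const R_xlen_t st = stride[ax];
    std::vector<double> f(len);
    std::vector<int> s(len);
    // iterate over all lines orthogonal to ax
    const int oa = (ax == 0) ? 1 : 0;
    const int ob = (ax == 2) ? 1 : 2;
    for (int b = 0; b < nn[ob]; ++b) {
      for (int a = 0; a < nn[oa]; ++a) {
        R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
        for (int q = 0; q < len; ++q) {
          f[q] = D[base + q * st];
          s[q] = S[base + q * st];
        }
        dt_line(f, s, len, spacing[ax]);
        for (int q = 0; q < len; ++q) {
          D[base + q * st] = f[q];
          S[base + q * st] = s[q];
        }
      }
    }
  }
  NumericVector dist2(n);
  IntegerVector idx(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dist2[i] = D[i];
    idx[i] = (S[i] < 0) ? NA_INTEGER : S[i] + 1;  // 1-based for R
  }
  return List::create(_["dist2"] = dist2, _["site"] = idx);
}

// 26-connected component labelling (iterative BFS).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x3 = (int)(v / ((R_xlen_t)n1 * n2));
      int r = (int)(v % ((R_xlen_t)n1 * n2));
      int x2 = r / n1;
      int x1 = r % n1;
      for (int d3 = -1; d3 <= 1; ++d3) {
        int y3 = x3 + d3; if (y3 < 0 || y3 >= n3) continue;
        for (int d2 = -1; d2 <= 1; ++d2) {
          int y2 = x2 + d2; if (y2 < 0 || y2 >= n2) continue;
          for (int d1 = -1; d1 <= 1; ++d1) {
            int y1 = x1 + d1; if (y1 < 0 || y1 >= n1) continue;
            R_xlen_t u = (R_xlen_t)y1 + (R_xlen_t)n1 * (y2 + (R_xlen_t)n2 * y3);
            if (mask[u] && lab[u] == 0) { lab[u] = cur; stack.push_back(u); }
          }
        }
      }
    }
  }
  return lab;
}

// Trilinear sampling of a volume at fractional voxel coordinates.
static double trilerp(const double *vol, int n1, int n2, int n3,
                      double x1, double x2, double x3, bool &inside) {
  if (x1 < 0 || x2 < 0 || x3 < 0 ||
      x1 > n1 - 1 || x2 > n2 - 1 || x3 > n3 - 1) { inside = false; return 0.0; }
  inside = true;
  int i1 = (int)std::floor(x1), i2 = (int)std::floor(x2), i3 = (int)std::floor(x3);
  if (i1 == n1 - 1) --i1;
  if (i2 == n2 - 1) --i2;
  if (i3 == n3 - 1) --i3;
  if (n1 == 1) i1 = 0;
  if (n2 == 1) i2 = 0;
  if (n3 == 1) i3 = 0;
  double t1 = x1 - i1, t2 = x2 - i2, t3 = x3 - i3;
  R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  int j1 = (n1 > 1) ? 1 : 0, j2 = (n2 > 1) ? 1 : 0, j3 = (n3 > 1) ? 1 : 0;
  R_xlen_t b = (R_xlen_t)i1 + s2 * i2 + s3 * i3;
  double c000 = vol[b], c100 = vol[b + j1];
  double c010 = vol[b + j2 * s2], c110 = vol[b + j1 + j2 * s2];
  double c001 = vol[b + j3 * s3], c101 = vol[b + j1 + j3 * s3];
  double c011 = vol[b + j2 * s2 + j3 * s3], c111 = vol[b + j1 + j2 * s2 + j3 * s3];
  double c00 = c000 * (1 - t1) + c100 * t1;
  double c10 = c010 * (1 - t1) + c110 * t1;
  double c01 = c001 * (1 - t1) + c101 * t1;
  double c11 = c011 * (1 - t1) + c111 * t1;
  double c0 = c00 * (1 - t2) + c10 * t2;
  double c1 = c01 * (1 - t2) + c11 * t2;
  return c0 * (1 - t3) + c1 * t3;
}

// [[Rcpp::export(name = ".resample_shift_cpp")]]
NumericVector resample_shift_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector shift_mm) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  const double *v = REAL(vol);
  double s1 = shift_mm[0] / spacing[0];
  double s2 = shift_mm[1] / spacing[1];
  double s3 = shift_mm[2] / spacing[2];
  R_xlen_t k = 0;
  for (int x3 = 0; x3 < n3; ++x3)
    for (int x2 = 0; x2 < n2; ++x2)
      for (int x1 = 0; x1 < n1; ++x1, ++k) {
        bool inside;
        double val = trilerp(v, n1, n2, n3, x1 - s1, x2 - s2, x3 - s3, inside);
        out[k] = inside ? val : 0.0;
      }
  return out;
}
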