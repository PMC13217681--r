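#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D squared-distance transform along a sampled line (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher), with physical sample spacing h.
// f holds squared distances (may be +Inf where no seed reaches yet).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + q * (double)q * h2) - (f[p] + p * (double)p * h2)) /
          (2.0 * h2 * (q - p));
      if (s <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; break; }
      } else {
        ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
        break;
      }
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    double diff = (double)(q - v[j]) * h;
    d[q] = diff * diff + f[v[j]];
  }
}

// 1D min-plus convolution with the flat-bottomed box kernel
// k(m) = ((|m| - 0.5) h)^2 for m != 0, 0 at m = 0: the per-axis term of the
// squared distance from a voxel centre to a seed voxel's *box*. Window w
// bounds the scan; early break is valid because f >= 0 and k grows in |m|.
static void boxconv1d(const std::vector<double>& f, std::vector<double>& d,
                      int n, double h, int w) {
  for (int x = 0; x < n; ++x) {
    double best = f[x];
    for (int m = 1; m <= w; ++m) {
      double k = (m - 0.5) * h;
      k *= k;
      if (k >= best) break;
      if (x - m >= 0 && f[x - m] + k < best) best = f[x - m] + k;
      if (x + m < n && f[x + m] + k < best) best = f[x + m] + k;
    }
    d[x] = best;
  }
}

// Squared distance (mm^2) from every voxel centre to the nearest seed-voxel
// *region* (the axis-aligned spacing-sized box around the seed centre);
// zero inside seed voxels. `cap` (mm) bounds the scan radius: values beyond
// it are only upper bounds, so callers must threshold below cap.
// [[Rcpp::export(name = ".region_dt_squared")]]
NumericVector region_dt_squared(LogicalVector seed, IntegerVector dim,
                                NumericVector spacing, double cap) {
  if (dim.size() != 3 || spacing.size() != 3)
    stop("dim and spacing must have length 3");
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n0 * n1 * n2;
  if (seed.size() != ntot) stop("seed length does not match dim");
  const double INF = std::numeric_limits<double>::infinity();

  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = seed[i] ? 0.0 : INF;

  int win[3];
  for (int a = 0; a < 3; ++a) {
    double wreal = R_finite(cap) ? std::ceil(cap / spacing[a] + 1.0) : 1e9;
    int nmaxa = (a == 0 ? n0 : (a == 1 ? n1 : n2)) - 1;
    win[a] = (int)std::min((double)nmaxa, wreal);
  }

  int nmax = std::max(n0, std::max(n1, n2));
  std::vector<double> f(nmax), d(nmax);

  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j) {
      R_xlen_t base = (R_xlen_t)k * n0 * n1 + (R_xlen_t)j * n0;
      for (int i = 0; i < n0; ++i) f[i] = out[base + i];
      boxconv1d(f, d, n0, spacing[0], win[0]);
      for (int i = 0; i < n0; ++i) out[base + i] = d[i];
    }
  for (int k = 0; k < n2; ++k)
    for (int i = 0; i < n0; ++i) {
      R_xlen_t base = (R_xlen_t)k * n0 * n1 + i;
      for (int j = 0; j < n1; ++j) f[j] = out[base + (R_xlen_t)j * n0];
      boxconv1d(f, d, n1, spacing[1], win[1]);
      for (int j = 0; j < n1; ++j) out[base + (R_xlen_t)j * n0] = d[j];
    }
  const R_xlen_t s2 = (R_xlen_t)n0 * n1;
  for (int j = 0; j < n1; ++j)
    for (int i = 0; i < n0; ++i) {
      R_xlen_t base = (R_xlen_t)j * n0 + i;
      for (int k = 0; k < n2; ++k) f[k] = out[base + (R_xlen_t)k * s2];
      boxconv1d(f, d, n2, spacing[2], win[2]);
      for (int k = 0; k < n2; ++k) out[base + (R_xlen_t)k * s2] = d[k];
    }
  return out;
}

// Exact Euclidean squared distance transform of a 3D grid with anisotropic
// voxel spacing. `seed` is a logical array (column-major, dims `dim`);
// returns, for every voxel, the squared physical distance (mm^2) to the
// nearest seed-voxel centre (+Inf if there are no seeds).
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector seed, IntegerVector dim,
                          NumericVector spacing) {
  if (dim.size() != 3 || spacing.size() != 3)
    stop("dim and spacing must have length 3");
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t ntot = (R_xlen_t)n0 * n1 * n2;
  if (seed.size() != ntot) stop("seed length does not match dim");
  const double INF = std::numeric_limits<double>::infinity();

  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = seed[i] ? 0.0 : INF;

  int nmax = std::max(n0, std::max(n1, n2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (stride 1)
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j) {
      R_xlen_t base = (R_xlen_t)k * n0 * n1 + (R_xlen_t)j * n0;
      for (int i = 0; i < n0; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n0, spacing[0]);
      for (int i = 0; i < n0; ++i) out[base + i] = d[i];
    }
  // axis 1 (stride n0)
  for (int k = 0; k < n2; ++k)
    for (int i = 0; i < n0; ++i) {
      R_xlen_t base = (R_xlen_t)k * n0 * n1 + i;
      for (int j = 0; j < n1; ++j) f[j] = out[base + (R_xlen_t)j * n0];
      dt1d(f, d, v, z, n1, spacing[1]);
      for (int j = 0; j < n1; ++j) out[base + (R_xlen_t)j * n0] = d[j];
    }
  // axis 2 (stride n0*n1)
  const R_xlen_t s2 = (R_xlen_t)n0 * n1;
  for (int j = 0; j < n1; ++j)
    for (int i = 0; i < n0; ++i) {
      R_xlen_t base = (R_xlen_t)j * n0 + i;
      for (int k = 0; k < n2; ++k) f[k] = out[base + (R_xlen_t)k * s2];
      dt1d(f, d, v, z, n2, spacing[2]);
      for (int k = 0; k < n2; ++k) out[base + (R_xlen_t)k * s2] = d[k];
    }
  return out;
}
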