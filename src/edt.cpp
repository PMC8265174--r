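#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb-Huttenlocher lower-envelope squared distance transform along
// one axis. f holds squared distances (um^2); w is the voxel spacing (um).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double num = (f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k]);
      double den = 2.0 * w2 * (q - v[k]);
      s = num / den;
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (um) from each foreground voxel to the nearest
// background voxel, anisotropy-aware. mask is an R logical array with
// dim = (nz, ny, nx); spacing = (sz, sy, sx) in um. Background voxels get 0.
// Volume faces are NOT treated as background (a vessel touching the border
// keeps its in-slab radius).
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  // large finite stand-in for "no background seed yet": true infinity breaks
  // the lower-envelope recursion (INF - INF = NaN)
  const double BIG = 1e15;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz;
      for (int q = 0; q < nz; ++q) f[q] = g[base + q];
      dt1d(f, d, v, z, nz, sz);
      for (int q = 0; q < nz; ++q) g[base + q] = d[q];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = (R_xlen_t)x * nz * ny + zz;
      for (int q = 0; q < ny; ++q) f[q] = g[base + (R_xlen_t)q * nz];
      dt1d(f, d, v, z, ny, sy);
      for (int q = 0; q < ny; ++q) g[base + (R_xlen_t)q * nz] = d[q];
    }
  // pass along x (stride nz*ny)
  const R_xlen_t sxy = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = (R_xlen_t)y * nz + zz;
      for (int q = 0; q < nx; ++q) f[q] = g[base + (R_xlen_t)q * sxy];
      dt1d(f, d, v, z, nx, sx);
      for (int q = 0; q < nx; ++q) g[base + (R_xlen_t)q * sxy] = d[q];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
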