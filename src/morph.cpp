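#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grayscale opening of a 2D slice by a spherical ("rolling ball")
// structuring element of radius r pixels: the background surface traced by
// rolling a ball of radius r under the intensity landscape.
//   erosion : e(p) = min_{d in B} [ f(p+d) - b(d) ]
//   opening : o(p) = max_{d in B} [ e(p-d) + b(d) ]
// with b(d) = sqrt(r^2 - |d|^2) for |d| <= r. Offsets falling outside the
// image are skipped (min/max over the valid domain only).
// img: ny x nx numeric matrix. Returns the background (opening).
// [[Rcpp::export(name = ".rollball_background_cpp")]]
NumericMatrix rollball_background_cpp(NumericMatrix img, double radius) {
  const int ny = img.nrow(), nx = img.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  // ball offsets and heights
  int ri = (int)std::floor(radius);
  std::vector<int> dy, dx;
  std::vector<double> h;
  for (int a = -ri; a <= ri; ++a)
    for (int b = -ri; b <= ri; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        dy.push_back(a);
        dx.push_back(b);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  const int m = (int)dy.size();

  NumericMatrix ero(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double mn = INF;
      for (int k = 0; k < m; ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double v = img(yy, xx) - h[k];
        if (v < mn) mn = v;
      }
      ero(y, x) = mn;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double mx = -INF;
      for (int k = 0; k < m; ++k) {
        int yy = y - dy[k], xx = x - dx[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        double v = ero(yy, xx) + h[k];
        if (v > mx) mx = v;
      }
      out(y, x) = mx;
    }
  return out;
}

// 26-connected component labeling of a logical 3D array (dim = nz, ny, nx).
// Returns an integer array: 0 = background, components numbered from 1 in
// first-encounter (column-major) order.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dyy = -1; dyy <= 1; ++dyy)
          for (int dxx = -1; dxx <= 1; ++dxx) {
            if (!dz && !dyy && !dxx) continue;
            int zz = z + dz, yy = y + dyy, xx = x + dxx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t q = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
            if (mask[q] && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
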