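#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a union of capsules (cylinders with hemispherical caps) into a
// logical 3D array with dim = (nz, ny, nx). Segment endpoints p0, p1 are
// n x 3 matrices of physical (z, y, x) coordinates in um; radius in um.
// Voxel (i, j, k) (1-based in R) has its center at ((i-0.5)*sz, ...).
// [[Rcpp::export(name = ".rasterize_capsules_cpp")]]
LogicalVector rasterize_capsules_cpp(NumericMatrix p0, NumericMatrix p1,
                                     NumericVector radius, IntegerVector dim,
                                     NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);

  for (int s = 0; s < p0.nrow(); ++s) {
    const double az = p0(s, 0), ay = p0(s, 1), ax = p0(s, 2);
    const double bz = p1(s, 0), by = p1(s, 1), bx = p1(s, 2);
    const double r = radius[s], r2 = r * r;
    const double uz = bz - az, uy = by - ay, ux = bx - ax;
    const double len2 = uz * uz + uy * uy + ux * ux;

    // bounding box in voxel indices (0-based)
    int iz0 = std::max(0, (int)std::floor((std::min(az, bz) - r) / sz - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + r) / sz));
    int iy0 = std::max(0, (int)std::floor((std::min(ay, by) - r) / sy - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + r) / sy));
    int ix0 = std::max(0, (int)std::floor((std::min(ax, bx) - r) / sx - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + r) / sx));

    for (int x = ix0; x <= ix1; ++x) {
      double cx = (x + 0.5) * sx;
      for (int y = iy0; y <= iy1; ++y) {
        double cy = (y + 0.5) * sy;
        for (int z = iz0; z <= iz1; ++z) {
          double cz = (z + 0.5) * sz;
          double wz = cz - az, wy = cy - ay, wx = cx - ax;
          double t = 0.0;
          if (len2 > 0.0) {
            t = (wz * uz + wy * uy + wx * ux) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double dz2 = wz - t * uz, dy2 = wy - t * uy, dx2 = wx - t * ux;
          double d2 = dz2 * dz2 + dy2 * dy2 + dx2 * dx2;
          if (d2 <= r2)
            out[(R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z] = true;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
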