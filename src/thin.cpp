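#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Distance-ordered homotopic thinning to a curve skeleton.
//
// A foreground voxel is "simple" (its removal preserves topology) under the
// (26, 6) connectivity pair iff, within its 3x3x3 neighborhood:
//   (a) the foreground voxels of N26 (center excluded) form exactly one
//       26-connected component, and
//   (b) the background voxels of N18 form exactly one 6-connected component
//       that is 6-adjacent to the center (Bertrand & Malandain
//       characterization, computed here by explicit local search).
// Border voxels are deleted in increasing order of their Euclidean distance
// transform (outward-in), except curve endpoints (<= 1 foreground
// 26-neighbor), which are preserved.

namespace {

struct Nbhd {
  // offset tables for the 3x3x3 block, index = (dz+1) + 3*(dy+1) + 9*(dx+1)
  int dz[27], dy[27], dx[27];
  bool n18[27];          // true if offset is in the 18-neighborhood
  int adj26[27][27];     // adjacency between offsets (26-adjacency)
  int nadj26[27];
  int adj6[27][27];      // 6-adjacency, restricted later to N18
  int nadj6[27];
  int faces[6];          // the 6 face-neighbor indices
  Nbhd() {
    int f = 0;
    for (int i = 0; i < 27; ++i) {
      dz[i] = i % 3 - 1;
      dy[i] = (i / 3) % 3 - 1;
      dx[i] = (i / 9) - 1;
      int nz0 = std::abs(dz[i]) + std::abs(dy[i]) + std::abs(dx[i]);
      n18[i] = (i != 13) && (nz0 <= 2);
      if (nz0 == 1) faces[f++] = i;
      nadj26[i] = 0;
      nadj6[i] = 0;
    }
    for (int i = 0; i < 27; ++i)
      for (int j = 0; j < 27; ++j) {
        if (i == j) continue;
        int az = std::abs(dz[i] - dz[j]);
        int ay = std::abs(dy[i] - dy[j]);
        int ax = std::abs(dx[i] - dx[j]);
        if (az <= 1 && ay <= 1 && ax <= 1) adj26[i][nadj26[i]++] = j;
        if (az + ay + ax == 1) adj6[i][nadj6[i]++] = j;
      }
  }
};

const Nbhd NB;

inline bool is_simple(const bool nb[27]) {
  // (a) one 26-component of foreground among the 26 neighbors
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27], top;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    if (++ncomp > 1) return false;
    top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top) {
      int p = stack[--top];
      for (int k = 0; k < NB.nadj26[p]; ++k) {
        int q = NB.adj26[p][k];
        if (q != 13 && nb[q] && !seen[q]) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  if (ncomp != 1) return false;  // isolated voxel: not simple

  // (b) one 6-component of background in N18, 6-adjacent to center
  for (int i = 0; i < 27; ++i) seen[i] = false;
  ncomp = 0;
  for (int fi = 0; fi < 6; ++fi) {
    int i = NB.faces[fi];
    if (nb[i] || seen[i]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top) {
      int p = stack[--top];
      for (int k = 0; k < NB.nadj6[p]; ++k) {
        int q = NB.adj6[p][k];
        if (NB.n18[q] && !nb[q] && !seen[q]) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return ncomp == 1;
}

}  // namespace

// [[Rcpp::export(name = ".skeletonize3d_cpp")]]
LogicalVector skeletonize3d_cpp(LogicalVector mask, IntegerVector dim,
                                NumericVector edt) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  auto idx_of = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z;
  };

  auto fill_nb = [&](R_xlen_t p, bool nb[27], int& nfg) {
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    nfg = 0;
    for (int i = 0; i < 27; ++i) {
      int zz = z + NB.dz[i], yy = y + NB.dy[i], xx = x + NB.dx[i];
      bool v = false;
      if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
        v = fg[idx_of(zz, yy, xx)] != 0;
      nb[i] = v;
      if (v && i != 13) ++nfg;
    }
  };

  auto is_border = [&](R_xlen_t p) {
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int fi = 0; fi < 6; ++fi) {
      int i = NB.faces[fi];
      int zz = z + NB.dz[i], yy = y + NB.dy[i], xx = x + NB.dx[i];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;  // volume faces are not background for border purposes
      if (!fg[idx_of(zz, yy, xx)]) return true;
    }
    return false;
  };

  // Deletion order: primary key = EDT (outward-in). Secondary key = the
  // maximum EDT among 26-neighbors, ascending: among border voxels of equal
  // depth, the ones far from the medial ridge go first, so the surviving
  // chain stays centered (e.g. at the flat end cap of a cylinder).
  std::vector<double> nbrmax(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!fg[i]) continue;
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((R_xlen_t)nz * ny));
    double mx = 0.0;
    for (int k = 0; k < 27; ++k) {
      if (k == 13) continue;
      int zz = z + NB.dz[k], yy = y + NB.dy[k], xx = x + NB.dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t q = idx_of(zz, yy, xx);
      if (fg[q] && edt[q] > mx) mx = edt[q];
    }
    nbrmax[i] = mx;
  }

  typedef std::pair<std::pair<double, double>, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  auto push_vox = [&](R_xlen_t i) {
    pq.push(QE(std::make_pair(edt[i], nbrmax[i]), i));
  };
  for (R_xlen_t i = 0; i < n; ++i)
    if (fg[i] && is_border(i)) push_vox(i);

  bool nb[27];
  int nfg;
  while (!pq.empty()) {
    R_xlen_t p = pq.top().second;
    pq.pop();
    if (!fg[p]) continue;
    fill_nb(p, nb, nfg);
    if (nfg <= 1) continue;        // curve endpoint: keep
    if (!is_simple(nb)) continue;  // would change topology: keep for now
    fg[p] = 0;
    // removal may make neighbors deletable
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int i = 0; i < 27; ++i) {
      if (i == 13) continue;
      int zz = z + NB.dz[i], yy = y + NB.dy[i], xx = x + NB.dx[i];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t q = idx_of(zz, yy, xx);
      if (fg[q]) push_vox(q);
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
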