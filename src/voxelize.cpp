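#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Watertight-mesh voxelization by parity ray casting.
//
// Vertices are given in continuous voxel-index coordinates; voxel centers
// sit at integer coordinates 0..n-1.  For every (j,k) row a ray parallel
// to the x axis is cast through all triangles; voxel centers with an odd
// number of surface crossings beyond them are inside.  Rays are jittered
// off the lattice, and any row whose crossings come degenerately close to
// a triangle edge is recomputed with a different jitter.

namespace {

// crossings of the vertical line (y, z) with the triangle set; returns
// false if a degenerate (edge-grazing) configuration was detected
bool row_crossings(const std::vector<int> &tris, const NumericMatrix &V,
                   const IntegerMatrix &F, double y, double z,
                   std::vector<double> &xs) {
  xs.clear();
  const double eps = 1e-10;
  for (int t : tris) {
    double y0 = V(F(t, 0), 1), z0 = V(F(t, 0), 2);
    double y1 = V(F(t, 1), 1), z1 = V(F(t, 1), 2);
    double y2 = V(F(t, 2), 1), z2 = V(F(t, 2), 2);
    double d = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
    double w1 = ((y - y0) * (z2 - z0) - (z - z0) * (y2 - y0));
    double w2 = ((y1 - y0) * (z - z0) - (z1 - z0) * (y - y0));
    if (std::abs(d) < eps) {
      // edge-on triangle: degenerate only if the line actually meets it
      double ylo = std::min({y0, y1, y2}) - eps, yhi = std::max({y0, y1, y2}) + eps;
      double zlo = std::min({z0, z1, z2}) - eps, zhi = std::max({z0, z1, z2}) + eps;
      if (y >= ylo && y <= yhi && z >= zlo && z <= zhi) return false;
      continue;
    }
    w1 /= d; w2 /= d;
    double w0 = 1.0 - w1 - w2;
    double tol = 1e-9;
    if (w0 < -tol || w1 < -tol || w2 < -tol) continue; // outside
    if (w0 < tol || w1 < tol || w2 < tol) return false; // grazing an edge
    xs.push_back(w0 * V(F(t, 0), 0) + w1 * V(F(t, 1), 0) + w2 * V(F(t, 2), 0));
  }
  std::sort(xs.begin(), xs.end());
  return true;
}

} // namespace

// [[Rcpp::export(name = ".voxelize_parity")]]
LogicalVector voxelize_parity_cpp(NumericMatrix V, IntegerMatrix F,
                                  IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);

  // bin triangles by the (j,k) rows their projection bbox touches
  std::vector<std::vector<int>> rows((size_t)ny * nz);
  for (int t = 0; t < F.nrow(); ++t) {
    double ylo = R_PosInf, yhi = R_NegInf, zlo = R_PosInf, zhi = R_NegInf;
    for (int v = 0; v < 3; ++v) {
      ylo = std::min(ylo, V(F(t, v), 1)); yhi = std::max(yhi, V(F(t, v), 1));
      zlo = std::min(zlo, V(F(t, v), 2)); zhi = std::max(zhi, V(F(t, v), 2));
    }
    int j0 = std::max(0, (int)std::floor(ylo - 1)), j1 = std::min(ny - 1, (int)std::ceil(yhi + 1));
    int k0 = std::max(0, (int)std::floor(zlo - 1)), k1 = std::min(nz - 1, (int)std::ceil(zhi + 1));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        rows[(size_t)j + (size_t)ny * k].push_back(t);
  }

  // jitter ladder: deterministic, irrational-ish offsets off the lattice
  const double jit[6][2] = {{7.07106781e-4, 1.2599210e-3},
                            {-9.4868330e-4, 6.2234898e-4},
                            {1.7320508e-3, -8.6602540e-4},
                            {-1.4142136e-3, -1.1180340e-3},
                            {2.2360680e-3, 1.7099759e-3},
                            {-2.6457513e-3, 2.2239801e-3}};

  std::vector<double> xs;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const std::vector<int> &tris = rows[(size_t)j + (size_t)ny * k];
      if (tris.empty()) continue;
      bool ok = false;
      for (int a = 0; a < 6 && !ok; ++a)
        ok = row_crossings(tris, V, F, j + jit[a][0], k + jit[a][1], xs);
      if (!ok) continue; // pathological row: leave background
      if (xs.empty()) continue;
      // parity: center i is inside iff an odd number of crossings lie beyond it
      size_t p = 0;
      for (int i = 0; i < nx; ++i) {
        while (p < xs.size() && xs[p] <= (double)i) ++p;
        if ((xs.size() - p) % 2 == 1)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return out;
}
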