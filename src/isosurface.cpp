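#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the Kuhn (Freudenthal)
// 6-tetrahedra subdivision of each grid cell.  The subdivision is
// face-to-face consistent across neighbouring cells (every cube face is
// split along its min-corner/max-corner diagonal), so the extracted
// surface is watertight by construction and free of the ambiguous-case
// holes of classic table-based marching cubes.
//
// Field values live at voxel centers with 0-based integer coordinates;
// output vertices are in the same (continuous) index space.

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  // dedup: iso-vertices live on grid edges keyed by their endpoint ids
  std::unordered_map<uint64_t, int> edge_vertex;
};

inline uint64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (uint64_t)a * 0x100000000ULL + (uint64_t)b;
}

// linear interpolation of the level crossing on edge (a, b)
inline int interp_vertex(MeshAcc &acc, int ga, int gb,
                         const double *pa, const double *pb,
                         double fa, double fb, double level) {
  uint64_t key = edge_key(ga, gb);
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  double t = (level - fa) / (fb - fa);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)acc.vx.size();
  acc.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  acc.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  acc.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  acc.edge_vertex.emplace(key, id);
  return id;
}

// orient triangle (i0,i1,i2) so its normal points toward decreasing field
// (outward for foreground > level); g is the linear field gradient in the tet
inline void push_tri(MeshAcc &acc, int i0, int i1, int i2, const double *g) {
  double ax = acc.vx[i1] - acc.vx[i0], ay = acc.vy[i1] - acc.vy[i0],
         az = acc.vz[i1] - acc.vz[i0];
  double bx = acc.vx[i2] - acc.vx[i0], by = acc.vy[i2] - acc.vy[i0],
         bz = acc.vz[i2] - acc.vz[i0];
  double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
  double d = nx * g[0] + ny * g[1] + nz * g[2];
  if (d > 0) std::swap(i1, i2); // normal must oppose the gradient
  acc.f0.push_back(i0);
  acc.f1.push_back(i1);
  acc.f2.push_back(i2);
}

} // namespace

// [[Rcpp::export(name = ".mtets_extract")]]
List mtets_extract(NumericVector field, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *F = field.begin();
  // Kuhn tetrahedra as corner bitmasks (bit0 = x, bit1 = y, bit2 = z)
  static const int tets[6][4] = {
      {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
      {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  MeshAcc acc;
  double P[8][3];
  int G[8];
  double Fv[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // gather cube corners
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          int lin = ci + nx * (cj + ny * ck);
          G[c] = lin;
          Fv[c] = F[lin];
          P[c][0] = ci; P[c][1] = cj; P[c][2] = ck;
          if (Fv[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int inside[4], nin = 0;
          for (int v = 0; v < 4; ++v) inside[v] = Fv[T[v]] > level ? 1 : 0, nin += inside[v];
          if (nin == 0 || nin == 4) continue;

          // linear field gradient over the tet (solve 3x3 by Cramer)
          double e[3][3], df[3];
          for (int r = 0; r < 3; ++r) {
            for (int c = 0; c < 3; ++c) e[r][c] = P[T[r + 1]][c] - P[T[0]][c];
            df[r] = Fv[T[r + 1]] - Fv[T[0]];
          }
          double det =
              e[0][0] * (e[1][1] * e[2][2] - e[1][2] * e[2][1]) -
              e[0][1] * (e[1][0] * e[2][2] - e[1][2] * e[2][0]) +
              e[0][2] * (e[1][0] * e[2][1] - e[1][1] * e[2][0]);
          double g[3];
          for (int c = 0; c < 3; ++c) {
            double m[3][3];
            for (int r = 0; r < 3; ++r)
              for (int cc = 0; cc < 3; ++cc)
                m[r][cc] = (cc == c) ? df[r] : e[r][cc];
            double dc =
                m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
            g[c] = dc / det;
          }

          // collect the in/out partition
          int in_v[4], out_v[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v)
            if (inside[v]) in_v[ni++] = T[v]; else out_v[no++] = T[v];

          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in_v[0] : out_v[0];
            int b = (nin == 1) ? out_v[0] : in_v[0];
            int c = (nin == 1) ? out_v[1] : in_v[1];
            int d = (nin == 1) ? out_v[2] : in_v[2];
            int p0 = interp_vertex(acc, G[a], G[b], P[a], P[b], Fv[a], Fv[b], level);
            int p1 = interp_vertex(acc, G[a], G[c], P[a], P[c], Fv[a], Fv[c], level);
            int p2 = interp_vertex(acc, G[a], G[d], P[a], P[d], Fv[a], Fv[d], level);
            push_tri(acc, p0, p1, p2, g);
          } else { // nin == 2: quad split into two triangles
            int a = in_v[0], b = in_v[1], c = out_v[0], d = out_v[1];
            int pac = interp_vertex(acc, G[a], G[c], P[a], P[c], Fv[a], Fv[c], level);
            int pad = interp_vertex(acc, G[a], G[d], P[a], P[d], Fv[a], Fv[d], level);
            int pbd = interp_vertex(acc, G[b], G[d], P[b], P[d], Fv[b], Fv[d], level);
            int pbc = interp_vertex(acc, G[b], G[c], P[b], P[c], Fv[b], Fv[c], level);
            push_tri(acc, pac, pad, pbd, g);
            push_tri(acc, pac, pbd, pbc, g);
          }
        }
      }

  int nv = (int)acc.vx.size(), nf = (int)acc.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fc(nf, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = acc.vx[v]; V(v, 1) = acc.vy[v]; V(v, 2) = acc.vz[v];
  }
  for (int f = 0; f < nf; ++f) {
    Fc(f, 0) = acc.f0[f]; Fc(f, 1) = acc.f1[f]; Fc(f, 2) = acc.f2[f];
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
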