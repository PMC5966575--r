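#include <Rcpp.h>
#include <vector>
#include <queue>
#include <functional>

using namespace Rcpp;

// Connected-component labelling of a 3-D binary array (BFS).
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> oi, oj, ok;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        oi.push_back(di); oj.push_back(dj); ok.push_back(dk);
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t m = 0; m < oi.size(); ++m) {
        int ii = i + oi[m], jj = j + oj[m], kk = k + ok[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !lab[w]) { lab[w] = cur; q.push(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Separable 1-D convolution along one axis (zero padding outside).
// axis: 0, 1 or 2; kernel length must be odd.
// [[Rcpp::export(name = ".convolve_axis")]]
NumericVector convolve_axis_cpp(NumericVector arr, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), kh = kl / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *A = arr.begin();
  double *O = out.begin();
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = nd[axis];
  const R_xlen_t sa = stride[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        double acc = 0.0;
        for (int m = 0; m < kl; ++m) {
          int p = pos + m - kh;
          if (p < 0 || p >= na) continue;
          acc += kernel[m] * A[idx + (R_xlen_t)(p - pos) * sa];
        }
        O[idx] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// Binary erosion/dilation with the 6- or 26-neighbourhood.
// op: 0 = erode, 1 = dilate.  Outside the grid counts as background.
// [[Rcpp::export(name = ".binary_morph")]]
LogicalVector binary_morph_cpp(LogicalVector mask, IntegerVector dim,
                               int connectivity, int op) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<int> oi, oj, ok;
  oi.push_back(0); oj.push_back(0); ok.push_back(0);
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        oi.push_back(di); oj.push_back(dj); ok.push_back(dk);
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        bool all_fg = true, any_fg = false;
        for (size_t m = 0; m < oi.size(); ++m) {
          int ii = i + oi[m], jj = j + oj[m], kk = k + ok[m];
          bool fg = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            fg = mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          if (fg) any_fg = true; else all_fg = false;
        }
        out[idx] = (op == 0) ? all_fg : any_fg;
      }
  out.attr("dim") = dim;
  return out;
}

// Union-find connected components of mesh vertices through face edges.
// faces: M x 3, 0-based.  Returns a 0-based component label per vertex
// (isolated vertices get their own component).
// [[Rcpp::export(name = ".vertex_components")]]
IntegerVector vertex_components_cpp(int n_vertices, IntegerMatrix faces) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = find(faces(f, 0)), b = find(faces(f, 1)), c = find(faces(f, 2));
    if (b != a) parent[b] = a;
    int a2 = find(a);
    if (c != a2) parent[find(c)] = a2;
  }
  IntegerVector lab(n_vertices);
  std::vector<int> remap(n_vertices, -1);
  int cur = 0;
  for (int i = 0; i < n_vertices; ++i) {
    int r = find(i);
    if (remap[r] < 0) remap[r] = cur++;
    lab[i] = remap[r];
  }
  lab.attr("n_components") = cur;
  return lab;
}
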