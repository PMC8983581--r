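// 3-D morphology primitives for anisotropic confocal volumes.
// Arrays are R arrays dim = c(nz, ny, nx), column-major: idx = z + nz*(y + ny*x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 6-connected component labelling of a logical mask.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int ni = idx3(zz, yy, xx, nz, ny);
        if (mask[ni] && lab[ni] == 0) {
          lab[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

struct WsNode {
  double value;
  long order;
  int index;
  int label;
};

struct WsCompare {
  // Max-heap on value; FIFO on insertion order for exact ties (determinism).
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value < b.value;
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding of `height` (descending) within `mask`.
// `seeds` carries positive labels at seed voxels, 0 elsewhere.
// [[Rcpp::export(name = ".watershed_3d")]]
IntegerVector watershed_3d(NumericVector height, IntegerVector seeds,
                           LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      pq.push(WsNode{height[i], order++, (int)i, seeds[i]});
    }
  }
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    if (lab[nd.index] != 0) continue;
    lab[nd.index] = nd.label;
    int x = nd.index / (nz * ny);
    int rem = nd.index - x * nz * ny;
    int y = rem / nz;
    int z = rem - y * nz;
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int ni = idx3(zz, yy, xx, nz, ny);
      if (mask[ni] && lab[ni] == 0) {
        pq.push(WsNode{height[ni], order++, ni, nd.label});
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher) with grid spacing h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = h2 * (q - p) * (q - p) + f[p];
  }
}

// Anisotropic Euclidean distance (physical units) from each true voxel of
// `mask` to the nearest false voxel. Voxels outside the stack count as
// background, so objects clipped at the border get small distances there.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  // large finite sentinel: true infinity breaks the envelope arithmetic
  // (INF - INF = NaN) in the first 1-D pass
  const double INF = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  // Border handling: seed one-half voxel beyond each face by clamping the
  // in-plane pass; approximate by treating border-adjacent outside voxels as
  // background at one spacing away. Implemented by padding each 1-D line with
  // a zero at both ends.
  std::vector<double> fbuf, dbuf;

  // pass along z
  fbuf.assign(nz + 2, 0.0); dbuf.assign(nz + 2, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) fbuf[z + 1] = g[idx3(z, y, x, nz, ny)];
      fbuf[0] = 0.0; fbuf[nz + 1] = 0.0;
      dt1d(fbuf, dbuf, hz, nz + 2);
      for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = dbuf[z + 1];
    }
  // pass along y
  fbuf.assign(ny + 2, 0.0); dbuf.assign(ny + 2, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) fbuf[y + 1] = g[idx3(z, y, x, nz, ny)];
      // lateral padding only adds background beyond the border:
      fbuf[0] = 0.0; fbuf[ny + 1] = 0.0;
      dt1d(fbuf, dbuf, hy, ny + 2);
      for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = dbuf[y + 1];
    }
  // pass along x
  fbuf.assign(nx + 2, 0.0); dbuf.assign(nx + 2, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) fbuf[x + 1] = g[idx3(z, y, x, nz, ny)];
      fbuf[0] = 0.0; fbuf[nx + 1] = 0.0;
      dt1d(fbuf, dbuf, hx, nx + 2);
      for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = dbuf[x + 1];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
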