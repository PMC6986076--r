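#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Seeded 3D watershed on the Euclidean distance transform of a binary mask,
// with anisotropic voxel spacing. Foreground components holding >= 2 seeds
// are partitioned by priority flooding in order of decreasing distance from
// the background; components with 0 or 1 seed are kept whole.

static inline R_xlen_t lin3(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), spacing s.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = R_NegInf; zb[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s, fq = f[q];
    while (true) {
      double sv = (double)v[k] * s;
      double sep = (fq + sq * sq - f[v[k]] - sv * sv) / (2 * sq - 2 * sv);
      if (sep <= zb[k]) { --k; }
      else {
        ++k; v[k] = q; zb[k] = sep; zb[k + 1] = R_PosInf;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zb[k + 1] < sq) ++k;
    double dv = sq - (double)v[k] * s;
    d[q] = dv * dv + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        double dy, double dx, double dz) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  const double big = 1e30;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? big : 0.0;
  std::vector<double> f, g;
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin3(y, x, z, ny, nx)];
      dt1d(f, g, dy);
      for (int y = 0; y < ny; ++y) d[lin3(y, x, z, ny, nx)] = g[y];
    }
  // pass along x
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin3(y, x, z, ny, nx)];
      dt1d(f, g, dx);
      for (int x = 0; x < nx; ++x) d[lin3(y, x, z, ny, nx)] = g[x];
    }
  // pass along z
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin3(y, x, z, ny, nx)];
      dt1d(f, g, dz);
      for (int z = 0; z < nz; ++z) d[lin3(y, x, z, ny, nx)] = g[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) d[i] = std::sqrt(d[i]);
  return d;
}

struct QItem {
  double prio;      // EDT value (flood from high to low)
  R_xlen_t idx;
  int label;
  long order;       // insertion order, final tie-break
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio < b.prio;   // max-heap on EDT
    if (a.idx != b.idx) return a.idx > b.idx;       // then raster order
    return a.order > b.order;                       // then first pushed
  }
};

// comps: component id per voxel (0 background); nseed: per component seed count.
// seeds: 0-based linear indices, all in foreground. Returns labels 1..K:
// seeded labels first in seed order, then unseeded components in raster order.
// [[Rcpp::export]]
IntegerVector ws3d_cpp(LogicalVector mask, IntegerVector dims,
                       IntegerVector comps, IntegerVector seedIdx,
                       NumericVector edt) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  int ncomp = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (comps[i] > ncomp) ncomp = comps[i];
  std::vector<int> nseed(ncomp + 1, 0);
  for (int s = 0; s < seedIdx.size(); ++s) ++nseed[comps[(R_xlen_t)seedIdx[s]]];

  IntegerVector lab(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;
  int nextLabel = 0;
  // seeds in multi-seed components flood; single-seed components are kept
  // whole but flooding from their seed covers them anyway.
  for (int s = 0; s < seedIdx.size(); ++s) {
    R_xlen_t i = (R_xlen_t)seedIdx[s];
    ++nextLabel;
    pq.push({edt[i], i, nextLabel, order++});
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (lab[it.idx] != 0) continue;
    lab[it.idx] = it.label;
    int z = it.idx / ((R_xlen_t)ny * nx);
    int rem = it.idx % ((R_xlen_t)ny * nx);
    int x = rem / ny, y = rem % ny;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dy && !dx && !dz) continue;
          int yy = y + dy, xx = x + dx, zz = z + dz;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;
          R_xlen_t u = lin3(yy, xx, zz, ny, nx);
          if (mask[u] && lab[u] == 0)
            pq.push({edt[u], u, it.label, order++});
        }
  }
  // unseeded components become single labels, in raster order of first voxel
  std::vector<int> compLabel(ncomp + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int cc = comps[i];
    if (cc == 0 || nseed[cc] > 0) continue;
    if (compLabel[cc] == 0) compLabel[cc] = ++nextLabel;
    lab[i] = compLabel[cc];
  }
  lab.attr("maxlabel") = nextLabel;
  return lab;
}
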