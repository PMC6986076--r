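#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D local-maxima finder with prominence ("tolerance") suppression.
//
// Voxels are processed in order of decreasing intensity while components are
// merged with a union-find structure (26-neighbourhood). When a component
// whose peak is lower meets a higher one at level h, its prominence is
// peak - h; it survives as a maximum iff prominence > tolerance. Components
// left at the end are measured against the global minimum. An intensity
// plateau yields a single seed at the centroid of the plateau, rounded to
// the nearest voxel.

static inline R_xlen_t lin3m(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
}

struct DSU {
  std::vector<int> parent;
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
};

// [[Rcpp::export]]
IntegerMatrix maxima3d_cpp(NumericVector img, IntegerVector dims,
                           double tolerance) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<R_xlen_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (img[a] != img[b]) return img[a] > img[b];
    return a < b;
  });

  DSU dsu;
  dsu.parent.assign(n, -1);               // -1 = not yet processed
  std::vector<double> peakVal(n, 0.0);
  std::vector<R_xlen_t> peakRep(n, 0);    // first (highest, earliest) voxel
  std::vector<R_xlen_t> accepted;

  std::vector<int> roots;
  for (R_xlen_t oi = 0; oi < n; ++oi) {
    R_xlen_t v = ord[oi];
    double val = img[v];
    int z = v / ((R_xlen_t)ny * nx);
    int rem = v % ((R_xlen_t)ny * nx);
    int x = rem / ny, y = rem % ny;
    roots.clear();
    for (int dz = -1; dz <= 1; ++dz)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dy && !dx && !dz) continue;
          int yy = y + dy, xx = x + dx, zz = z + dz;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;
          R_xlen_t u = lin3m(yy, xx, zz, ny, nx);
          if (dsu.parent[u] == -1) continue;
          int r = dsu.find((int)u);
          if (std::find(roots.begin(), roots.end(), r) == roots.end())
            roots.push_back(r);
        }
    if (roots.empty()) {
      dsu.parent[v] = (int)v;
      peakVal[v] = val;
      peakRep[v] = v;
      continue;
    }
    // main root: highest peak, earliest representative on ties
    int main = roots[0];
    for (size_t k = 1; k < roots.size(); ++k) {
      int r = roots[k];
      if (peakVal[r] > peakVal[main] ||
          (peakVal[r] == peakVal[main] && peakRep[r] < peakRep[main]))
        main = r;
    }
    for (size_t k = 0; k < roots.size(); ++k) {
      int r = roots[k];
      if (r == main) continue;
      if (peakVal[r] - val > tolerance) accepted.push_back(peakRep[r]);
      dsu.parent[r] = main;
    }
    dsu.parent[v] = main;
  }
  // surviving components: prominence relative to the global minimum
  double gmin = img[ord[n - 1]];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (dsu.parent[i] == (int)i && peakVal[i] - gmin > tolerance)
      accepted.push_back(peakRep[i]);
  }
  std::sort(accepted.begin(), accepted.end(),
            [&](R_xlen_t a, R_xlen_t b) {
              if (img[a] != img[b]) return img[a] > img[b];
              return a < b;
            });

  // plateau centroid for each accepted representative (0-based voxel coords)
  IntegerMatrix out((int)accepted.size(), 3);
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack;
  for (size_t s = 0; s < accepted.size(); ++s) {
    R_xlen_t rep = accepted[s];
    double val = img[rep];
    double sy = 0, sx = 0, sz = 0;
    R_xlen_t cnt = 0;
    stack.clear();
    stack.push_back(rep);
    std::vector<R_xlen_t> visited;
    seen[rep] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      visited.push_back(v);
      int z = v / ((R_xlen_t)ny * nx);
      int rem = v % ((R_xlen_t)ny * nx);
      int x = rem / ny, y = rem % ny;
      sy += y; sx += x; sz += z; ++cnt;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dy && !dx && !dz) continue;
            int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                zz < 0 || zz >= nz)
              continue;
            R_xlen_t u = lin3m(yy, xx, zz, ny, nx);
            if (!seen[u] && img[u] == val) { seen[u] = 1; stack.push_back(u); }
          }
    }
    for (R_xlen_t v : visited) seen[v] = 0;
    out(s, 0) = (int)std::llround(sy / cnt);
    out(s, 1) = (int)std::llround(sx / cnt);
    out(s, 2) = (int)std::llround(sz / cnt);
  }
  return out;
}
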