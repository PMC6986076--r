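#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 26-connected labeling and calibrated measurement of 3D binary objects.
// Arrays are passed flattened in R's column-major order with dim = (ny, nx, nz);
// slice 1 is the basal (glass-side) slice.

static inline R_xlen_t lin(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
}

// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = v / ((R_xlen_t)ny * nx);
      int rem = v % ((R_xlen_t)ny * nx);
      int x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dy && !dx && !dz) continue;
            int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            R_xlen_t u = lin(yy, xx, zz, ny, nx);
            if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
          }
    }
  }
  lab.attr("maxlabel") = next;
  return lab;
}

// Per-label voxel count, intensity stats, centroid sums, bounding box and
// exposed-face counts by orientation (for anisotropic surface area).
// labels: integer label array; img: intensity array (same shape).
// [[Rcpp::export]]
DataFrame region_stats3d_cpp(IntegerVector labels, IntegerVector dims,
                             NumericVector img) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  int K = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (labels[i] > K) K = labels[i];
  std::vector<double> sumy(K, 0), sumx(K, 0), sumz(K, 0), isum(K, 0);
  std::vector<double> imax(K, R_NegInf);
  std::vector<R_xlen_t> nvox(K, 0);
  std::vector<int> fy(K, 0), fx(K, 0), fz(K, 0); // exposed faces per axis
  std::vector<int> y0(K, INT_MAX), y1(K, -1), x0(K, INT_MAX), x1(K, -1),
                   z0(K, INT_MAX), z1(K, -1);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = lin(y, x, z, ny, nx);
        int L = labels[i];
        if (L == 0) continue;
        int k = L - 1;
        ++nvox[k];
        sumy[k] += y; sumx[k] += x; sumz[k] += z;
        double v = img[i];
        isum[k] += v;
        if (v > imax[k]) imax[k] = v;
        if (y < y0[k]) y0[k] = y; if (y > y1[k]) y1[k] = y;
        if (x < x0[k]) x0[k] = x; if (x > x1[k]) x1[k] = x;
        if (z < z0[k]) z0[k] = z; if (z > z1[k]) z1[k] = z;
        // faces exposed towards +-y, +-x, +-z (different label or outside)
        if (y == 0      || labels[lin(y - 1, x, z, ny, nx)] != L) ++fy[k];
        if (y == ny - 1 || labels[lin(y + 1, x, z, ny, nx)] != L) ++fy[k];
        if (x == 0      || labels[lin(y, x - 1, z, ny, nx)] != L) ++fx[k];
        if (x == nx - 1 || labels[lin(y, x + 1, z, ny, nx)] != L) ++fx[k];
        if (z == 0      || labels[lin(y, x, z - 1, ny, nx)] != L) ++fz[k];
        if (z == nz - 1 || labels[lin(y, x, z + 1, ny, nx)] != L) ++fz[k];
      }
  IntegerVector label(K), nv(K), by0(K), by1(K), bx0(K), bx1(K), bz0(K), bz1(K),
               facesY(K), facesX(K), facesZ(K);
  NumericVector cy(K), cx(K), cz(K), imean(K), imx(K);
  for (int k = 0; k < K; ++k) {
    label[k] = k + 1;
    nv[k] = (int)nvox[k];
    double m = nvox[k] > 0 ? (double)nvox[k] : 1.0;
    cy[k] = sumy[k] / m; cx[k] = sumx[k] / m; cz[k] = sumz[k] / m;
    imean[k] = isum[k] / m;
    imx[k] = nvox[k] > 0 ? imax[k] : NA_REAL;
    by0[k] = y0[k]; by1[k] = y1[k]; bx0[k] = x0[k]; bx1[k] = x1[k];
    bz0[k] = z0[k]; bz1[k] = z1[k];
    facesY[k] = fy[k]; facesX[k] = fx[k]; facesZ[k] = fz[k];
  }
  return DataFrame::create(
    _["label"] = label, _["nvox"] = nv,
    _["cy"] = cy, _["cx"] = cx, _["cz"] = cz,
    _["meanInt"] = imean, _["maxInt"] = imx,
    _["y0"] = by0, _["y1"] = by1, _["x0"] = bx0, _["x1"] = bx1,
    _["z0"] = bz0, _["z1"] = bz1,
    _["facesY"] = facesY, _["facesX"] = facesX, _["facesZ"] = facesZ);
}
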