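#include <Rcpp.h>
#include <cmath>
#include <deque>
using namespace Rcpp;

// Windowed auto-local threshold over a circular (disc) domain of radius r.
//
// A pixel is OBJECT iff p > S - c, where S is the mean, mid-gray
// ((max+min)/2) or median of the 8-bit grey values inside the disc centred
// on the pixel, clipped to the image (no padding). Median of an even-sized
// window is the lower middle order statistic.
//
// Each statistic uses a specialized exact algorithm:
//   mean    - per-column prefix sums combined per disc column offset;
//   midgray - per-column sliding min/max (monotonic deques) per distinct
//             disc half-height, combined across offsets;
//   median  - sliding 256-bin histogram down each column with a running
//             median pointer (Huang's algorithm).

static std::vector<int> discHalfHeights(int r) {
  std::vector<int> halfh(2 * r + 1);
  for (int dx = -r; dx <= r; ++dx)
    halfh[dx + r] = (int)std::floor(std::sqrt((double)r * r - (double)dx * dx));
  return halfh;
}

static void altMean(const int *img, int ny, int nx, int r, double c,
                    int *out) {
  std::vector<int> halfh = discHalfHeights(r);
  // column prefix sums: P[y + 1, x] = sum img[0..y, x]
  std::vector<double> P((ny + 1) * (size_t)nx);
  for (int x = 0; x < nx; ++x) {
    const int *col = img + (size_t)x * ny;
    double *p = &P[(size_t)x * (ny + 1)];
    p[0] = 0;
    for (int y = 0; y < ny; ++y) p[y + 1] = p[y] + col[y];
  }
  std::vector<double> sum((size_t)ny * nx, 0.0);
  std::vector<int> cnt((size_t)ny * nx, 0);
  for (int dx = -r; dx <= r; ++dx) {
    int h = halfh[dx + r];
    for (int x = 0; x < nx; ++x) {
      int xx = x + dx;
      if (xx < 0 || xx >= nx) continue;
      const double *p = &P[(size_t)xx * (ny + 1)];
      double *s = &sum[(size_t)x * ny];
      int *k = &cnt[(size_t)x * ny];
      for (int y = 0; y < ny; ++y) {
        int lo = y - h; if (lo < 0) lo = 0;
        int hi = y + h + 1; if (hi > ny) hi = ny;
        s[y] += p[hi] - p[lo];
        k[y] += hi - lo;
      }
    }
  }
  for (size_t i = 0; i < (size_t)ny * nx; ++i)
    out[i] = ((double)img[i] > sum[i] / (double)cnt[i] - c);
}

// sliding min and max down one column for centred window half-height h
static void slideMinMax(const int *col, int ny, int h, int *mn, int *mx) {
  std::deque<int> qmin, qmax;
  for (int y = 0; y < ny + h; ++y) {
    if (y < ny) {
      while (!qmin.empty() && col[qmin.back()] >= col[y]) qmin.pop_back();
      qmin.push_back(y);
      while (!qmax.empty() && col[qmax.back()] <= col[y]) qmax.pop_back();
      qmax.push_back(y);
    }
    int center = y - h;
    if (center < 0) continue;
    if (center >= ny) break;
    while (qmin.front() < center - h) qmin.pop_front();
    while (qmax.front() < center - h) qmax.pop_front();
    mn[center] = col[qmin.front()];
    mx[center] = col[qmax.front()];
  }
}

static void altMidgray(const int *img, int ny, int nx, int r, double c,
                       int *out) {
  std::vector<int> halfh = discHalfHeights(r);
  std::vector<int> gmin((size_t)ny * nx, 255), gmax((size_t)ny * nx, 0);
  // per distinct half-height: column-sliding extrema, combined at +-dx
  std::vector<int> cmn((size_t)ny * nx), cmx((size_t)ny * nx);
  for (int adx = 0; adx <= r; ++adx) {
    int h = halfh[adx + r];
    if (adx > 0 && h == halfh[adx - 1 + r]) {
      // same half-height as previous offset: reuse cmn/cmx
    } else {
      for (int x = 0; x < nx; ++x)
        slideMinMax(img + (size_t)x * ny, ny, h, &cmn[(size_t)x * ny],
                    &cmx[(size_t)x * ny]);
    }
    for (int sgn = -1; sgn <= 1; sgn += 2) {
      if (adx == 0 && sgn == 1) continue;
      int dx = sgn * adx;
      for (int x = 0; x < nx; ++x) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        const int *a = &cmn[(size_t)xx * ny];
        const int *b = &cmx[(size_t)xx * ny];
        int *gm = &gmin[(size_t)x * ny];
        int *gM = &gmax[(size_t)x * ny];
        for (int y = 0; y < ny; ++y) {
          if (a[y] < gm[y]) gm[y] = a[y];
          if (b[y] > gM[y]) gM[y] = b[y];
        }
      }
    }
  }
  for (size_t i = 0; i < (size_t)ny * nx; ++i)
    out[i] = ((double)img[i] > (gmin[i] + gmax[i]) * 0.5 - c);
}

static void altMedian(const int *img, int ny, int nx, int r, double c,
                      int *out) {
  std::vector<int> halfh = discHalfHeights(r);
  int hist[256];
  for (int x = 0; x < nx; ++x) {
    std::fill(hist, hist + 256, 0);
    int count = 0, med = 0, below = 0;  // below = # elements < med
    for (int dx = -r; dx <= r; ++dx) {
      int xx = x + dx;
      if (xx < 0 || xx >= nx) continue;
      const int *col = img + (size_t)xx * ny;
      int h = halfh[dx + r];
      int hi = h < ny - 1 ? h : ny - 1;
      for (int yy = 0; yy <= hi; ++yy) {
        int v = col[yy];
        ++hist[v]; ++count; if (v < med) ++below;
      }
    }
    for (int y = 0; y < ny; ++y) {
      if (y > 0) {
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          const int *col = img + (size_t)xx * ny;
          int h = halfh[dx + r];
          int yout = y - 1 - h, yin = y + h;
          if (yout >= 0) {
            int v = col[yout];
            --hist[v]; --count; if (v < med) --below;
          }
          if (yin < ny) {
            int v = col[yin];
            ++hist[v]; ++count; if (v < med) ++below;
          }
        }
      }
      int rank = (count + 1) / 2;  // lower middle for even windows
      while (below + hist[med] < rank) { below += hist[med]; ++med; }
      while (below >= rank) { --med; below -= hist[med]; }
      out[y + (size_t)x * ny] = ((double)img[y + (size_t)x * ny] >
                                 (double)med - c);
    }
  }
}

// [[Rcpp::export]]
LogicalMatrix alt_cpp(IntegerMatrix img, int method, int r, double c) {
  const int ny = img.nrow(), nx = img.ncol();
  if (r < 1) stop("domain radius r must be >= 1");
  std::vector<int> buf(img.begin(), img.end());
  std::vector<int> res((size_t)ny * nx);
  if (method == 1) altMean(buf.data(), ny, nx, r, c, res.data());
  else if (method == 2) altMidgray(buf.data(), ny, nx, r, c, res.data());
  else altMedian(buf.data(), ny, nx, r, c, res.data());
  LogicalMatrix out(ny, nx);
  std::copy(res.begin(), res.end(), out.begin());
  return out;
}
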