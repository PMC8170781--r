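#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labelling with deterministic ids: components are
// numbered by the raster order (column-major over rows, i.e. topmost then
// leftmost in 0-based (x=col, y=row) coordinates) of their first pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix &mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dx8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[4] = {-1, 0, 0, 1};
  const int dy4[4] = {-1, 1, 0, 0};
  // scan rows within columns? id order contract: raster order of the
  // topmost-leftmost pixel -> iterate y (rows) outer, x (cols) inner.
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        q.push(std::make_pair(i, j));
        while (!q.empty()) {
          std::pair<int, int> p = q.front();
          q.pop();
          int n = (connectivity == 8) ? 8 : 4;
          for (int d = 0; d < n; ++d) {
            int ni = p.first + (connectivity == 8 ? dx8[d] : dx4[d]);
            int nj = p.second + (connectivity == 8 ? dy8[d] : dy4[d]);
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Boundary tracing (radial sweep over the 8-neighbourhood, clockwise in
// image coordinates with y pointing down) of the foreground component that
// contains the raster-first foreground pixel. Returns an n x 2 matrix of
// 0-based (x, y) pixel coordinates forming an ordered closed contour
// (start pixel not repeated at the end); pixels may appear twice where the
// contour doubles back along one-pixel-wide spurs.
// [[Rcpp::export(name = ".trace_boundary")]]
IntegerMatrix trace_boundary(const IntegerMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int si = -1, sj = -1;
  for (int i = 0; i < H && si < 0; ++i)
    for (int j = 0; j < W; ++j)
      if (mask(i, j) != 0) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // neighbourhood in clockwise order starting from West:
  // W, NW, N, NE, E, SE, S, SW  (di = row offset, dj = col offset)
  const int di[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> xs, ys;
  xs.push_back(sj); ys.push_back(si);
  int ci = si, cj = sj;
  int prevdir = 0;               // direction from current pixel to previous
  int seci = -1, secj = -1;      // second pixel of the trace
  const long guard_max = 8L * H * W + 8;
  for (long guard = 0; guard < guard_max; ++guard) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (prevdir + k) % 8;
      int ni = ci + di[d], nj = cj + dj[d];
      if (ni >= 0 && ni < H && nj >= 0 && nj < W && mask(ni, nj) != 0) {
        found = d;
        break;
      }
    }
    if (found < 0) break; // isolated pixel
    int ni = ci + di[found], nj = cj + dj[found];
    if (ci == si && cj == sj) {
      if (seci >= 0 && ni == seci && nj == secj) break; // closed the loop
      if (seci < 0) { seci = ni; secj = nj; }
    }
    xs.push_back(nj); ys.push_back(ni);
    prevdir = (found + 4) % 8;
    ci = ni; cj = nj;
  }
  size_t n = xs.size();
  if (n > 1 && xs.back() == xs.front() && ys.back() == ys.front()) --n;
  IntegerMatrix out(n, 2);
  for (size_t k = 0; k < n; ++k) {
    out(k, 0) = xs[k];
    out(k, 1) = ys[k];
  }
  return out;
}

// k x k median filter on an integer label map, replicate borders.
// [[Rcpp::export(name = ".median_filter_int")]]
IntegerMatrix median_filter_int(const IntegerMatrix &img, int k) {
  const int H = img.nrow(), W = img.ncol(), r = k / 2;
  IntegerMatrix out(H, W);
  std::vector<int> buf(k * k);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int cj = std::min(std::max(j + dj, 0), W - 1);
        for (int di = -r; di <= r; ++di) {
          int ci = std::min(std::max(i + di, 0), H - 1);
          buf[n++] = img(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}
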