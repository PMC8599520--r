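#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Binary morphology on 0/1 integer matrices, pixel (x, y) at m(y, x).
// Definitions follow the set forms with the *reflected* structuring
// element: erosion(A)  = { z | (B-hat)_z subset of A }
//          dilation(A) = { z | (B-hat)_z intersects A }
// so (B-hat)_z = { z - o : o an anchor-relative offset of B }.
// Pixels outside the image are treated as 0 for both operations.

static void se_offsets(const IntegerMatrix& se, int ax, int ay,
                       std::vector<int>& ox, std::vector<int>& oy) {
  for (int r = 0; r < se.nrow(); ++r)
    for (int c = 0; c < se.ncol(); ++c)
      if (se(r, c) != 0) { ox.push_back(c - ax); oy.push_back(r - ay); }
}

// [[Rcpp::export]]
IntegerMatrix cpp_erode(const IntegerMatrix& a, const IntegerMatrix& se,
                        int ax, int ay) {
  std::vector<int> ox, oy;
  se_offsets(se, ax, ay, ox, oy);
  const int h = a.nrow(), w = a.ncol(), n = (int)ox.size();
  IntegerMatrix out(h, w);
  const int* pa = a.begin();
  int* po = out.begin();
  // interior pixels skip the bounds test; border band checks it
  int mx0 = 0, mx1 = 0, my0 = 0, my1 = 0;
  for (int k = 0; k < n; ++k) {
    if (-ox[k] < mx0) mx0 = -ox[k];
    if (-ox[k] > mx1) mx1 = -ox[k];
    if (-oy[k] < my0) my0 = -oy[k];
    if (-oy[k] > my1) my1 = -oy[k];
  }
  for (int x = 0; x < w; ++x) {
    const bool xin = (x + mx0 >= 0) && (x + mx1 < w);
    for (int y = 0; y < h; ++y) {
      const bool interior = xin && (y + my0 >= 0) && (y + my1 < h);
      int ok = 1;
      if (interior) {
        for (int k = 0; k < n; ++k)
          if (pa[(size_t)(x - ox[k]) * h + (y - oy[k])] == 0) { ok = 0; break; }
      } else {
        for (int k = 0; k < n; ++k) {
          const int qx = x - ox[k], qy = y - oy[k];
          if (qx < 0 || qx >= w || qy < 0 || qy >= h ||
              pa[(size_t)qx * h + qy] == 0) { ok = 0; break; }
        }
      }
      po[(size_t)x * h + y] = ok;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_dilate(const IntegerMatrix& a, const IntegerMatrix& se,
                         int ax, int ay) {
  std::vector<int> ox, oy;
  se_offsets(se, ax, ay, ox, oy);
  const int h = a.nrow(), w = a.ncol(), n = (int)ox.size();
  IntegerMatrix out(h, w);
  const int* pa = a.begin();
  int* po = out.begin();
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (pa[(size_t)x * h + y] != 0)
        for (int k = 0; k < n; ++k) {
          const int qx = x + ox[k], qy = y + oy[k];
          if (qx >= 0 && qx < w && qy >= 0 && qy < h)
            po[(size_t)qx * h + qy] = 1;
        }
  return out;
}

// 8-connected component labeling; labels 1..n assigned in raster-scan
// order of each component's first (topmost, then leftmost) pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& a) {
  const int h = a.nrow(), w = a.ncol();
  IntegerMatrix lab(h, w);
  const int* pa = a.begin();
  int* pl = lab.begin();
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      const size_t i = (size_t)x * h + y;
      if (pa[i] == 0 || pl[i] != 0) continue;
      ++next;
      pl[i] = next;
      stack.push_back(y * w + x);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int py = p / w, px = p % w;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int qy = py + dy, qx = px + dx;
            if (qy < 0 || qy >= h || qx < 0 || qx >= w) continue;
            const size_t q = (size_t)qx * h + qy;
            if (pa[q] != 0 && pl[q] == 0) {
              pl[q] = next;
              stack.push_back(qy * w + qx);
            }
          }
      }
    }
  }
  return lab;
}
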