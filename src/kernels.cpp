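#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Sliding-window median filter for non-negative integer-valued images
// (16-bit range). Huang's running-histogram algorithm with a two-level
// (coarse 256 / fine 65536) histogram; borders are handled by clamping
// (edge replication), so the window always holds (2r+1)^2 samples.
// [[Rcpp::export(name = ".median_filter_int")]]
IntegerMatrix median_filter_int(const IntegerMatrix& img, int radius) {
  const int h = img.nrow(), w = img.ncol();
  IntegerMatrix out(h, w);
  if (radius <= 0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  const int side = 2 * radius + 1;
  const int n = side * side;
  const int kth = (n + 1) / 2; // median position (1-based)
  std::vector<int> fine(65536), coarse(256);

  auto clampi = [](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };

  for (int i = 0; i < h; ++i) {
    std::fill(fine.begin(), fine.end(), 0);
    std::fill(coarse.begin(), coarse.end(), 0);
    // initialize window centered at (i, 0)
    for (int dj = -radius; dj <= radius; ++dj) {
      int j = clampi(dj, 0, w - 1);
      for (int di = -radius; di <= radius; ++di) {
        int ii = clampi(i + di, 0, h - 1);
        int v = img(ii, j);
        if (v < 0 || v > 65535) stop("pixel value outside 0..65535");
        ++fine[v];
        ++coarse[v >> 8];
      }
    }
    for (int j = 0; j < w; ++j) {
      if (j > 0) {
        int jr = clampi(j + radius, 0, w - 1);
        int jl = clampi(j - 1 - radius, 0, w - 1);
        for (int di = -radius; di <= radius; ++di) {
          int ii = clampi(i + di, 0, h - 1);
          int va = img(ii, jr), vr = img(ii, jl);
          ++fine[va]; ++coarse[va >> 8];
          --fine[vr]; --coarse[vr >> 8];
        }
      }
      // locate k-th smallest through coarse then fine bins
      int cnt = 0, cb = 0;
      while (cnt + coarse[cb] < kth) cnt += coarse[cb++];
      int v = cb << 8;
      while (cnt + fine[v] < kth) cnt += fine[v++];
      out(i, j) = v;
    }
  }
  return out;
}

// Connected-component labeling of a binary mask (4- or 8-connectivity).
// Returns an integer matrix: 0 = background, components numbered from 1 in
// raster-scan order of their first pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  stack.reserve(1024);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * h);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % h, pj = p / h;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + dx8[k], qj = pj + dy8[k];
          if (qi < 0 || qi >= h || qj < 0 || qj >= w) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * h);
          }
        }
      }
    }
  }
  return lab;
}

// Binary erosion by a disk (dx^2 + dy^2 <= r^2) or square (Chebyshev r)
// structuring element. Pixels within r of the border erode away unless the
// mask extends to the border on that side (out-of-frame treated as false).
// [[Rcpp::export(name = ".erode_mask")]]
LogicalMatrix erode_mask(const LogicalMatrix& mask, int radius, bool disk) {
  const int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix out(h, w);
  std::vector<std::pair<int, int>> offs;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (!disk || di * di + dj * dj <= radius * radius)
        offs.push_back({di, dj});
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) { out(i, j) = FALSE; continue; }
      bool keep = true;
      for (const auto& o : offs) {
        int qi = i + o.first, qj = j + o.second;
        if (qi < 0 || qi >= h || qj < 0 || qj >= w || !mask(qi, qj)) {
          keep = false;
          break;
        }
      }
      out(i, j) = keep;
    }
  }
  return out;
}

static inline int at(const std::vector<unsigned char>& m, int h, int w,
                     int i, int j) {
  if (i < 0 || i >= h || j < 0 || j >= w) return 0;
  return m[i + j * h];
}

// Zhang-Suen thinning: reduces a binary mask to its 8-connected,
// one-pixel-wide skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<unsigned char> m(h * (size_t)w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      m[i + j * (size_t)h] = mask(i, j) ? 1 : 0;

  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          if (!m[i + j * (size_t)h]) continue;
          // clockwise neighbors from north: p2..p9
          int p2 = at(m, h, w, i - 1, j),     p3 = at(m, h, w, i - 1, j + 1);
          int p4 = at(m, h, w, i, j + 1),     p5 = at(m, h, w, i + 1, j + 1);
          int p6 = at(m, h, w, i + 1, j),     p7 = at(m, h, w, i + 1, j - 1);
          int p8 = at(m, h, w, i, j - 1),     p9 = at(m, h, w, i - 1, j - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * h);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (int p : kill) m[p] = 0;
      }
    }
  }
  LogicalMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = m[i + j * (size_t)h] != 0;
  return out;
}
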