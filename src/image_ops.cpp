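#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter with edge replication. Intensities are small integers, so a
// per-window counting sort over the gathered values is plenty fast at the
// image sizes this package targets.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int window) {
  const int H = img.nrow(), W = img.ncol(), r = window / 2;
  IntegerMatrix out(H, W);
  std::vector<int> buf(window * window);
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

// 8-connected component labeling of a logical matrix by iterative flood
// fill (explicit stack). Labels are 1..n_components in first-encounter
// (column-major) order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& fg) {
  const int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (fg(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
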