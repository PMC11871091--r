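// Binary morphology on 2-D masks: connected-component labelling and
// dilation/erosion with arbitrary structuring-element offsets.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int ndir = (connectivity == 4) ? 4 : 8;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      lab(i0, j0) = next;
      stack.clear();
      stack.push_back(i0 + j0 * H);
      while (!stack.empty()) {
        const int q = stack.back(); stack.pop_back();
        const int qi = q % H, qj = q / H;
        for (int d = 0; d < ndir; ++d) {
          const int ni = qi + di[d], nj = qj + dj[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  }
  return lab;
}

// offsets: matrix with columns (di, dj)
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, const IntegerMatrix& offsets) {
  const int H = mask.nrow(), W = mask.ncol(), K = offsets.nrow();
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      for (int k = 0; k < K; ++k) {
        const int ni = i + offsets(k, 0), nj = j + offsets(k, 1);
        if (ni >= 0 && ni < H && nj >= 0 && nj < W) out(ni, nj) = true;
      }
    }
  return out;
}

// erosion: pixel survives if all offsets (within image) are foreground;
// off-image neighbours count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, const IntegerMatrix& offsets) {
  const int H = mask.nrow(), W = mask.ncol(), K = offsets.nrow();
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      bool keep = true;
      for (int k = 0; k < K; ++k) {
        const int ni = i + offsets(k, 0), nj = j + offsets(k, 1);
        if (ni < 0 || ni >= H || nj < 0 || nj >= W || !mask(ni, nj)) {
          keep = false; break;
        }
      }
      out(i, j) = keep;
    }
  return out;
}
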