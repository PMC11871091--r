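// Surface-distance support: boundary extraction (4-connectivity, image border
// counts as outside) and directed mean nearest-boundary distances.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
LogicalMatrix cpp_boundary4(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      bool edge = (i == 0 || i == H - 1 || j == 0 || j == W - 1);
      if (!edge)
        edge = !mask(i - 1, j) || !mask(i + 1, j) || !mask(i, j - 1) ||
               !mask(i, j + 1);
      out(i, j) = edge;
    }
  return out;
}

// coords: n x 2 matrices of (row, col) positions (1-based irrelevant: only
// differences are used). spacing: c(row_mm, col_mm). Returns the two
// directed mean distances c(mean_{a->b}, mean_{b->a}).
// [[Rcpp::export]]
NumericVector cpp_directed_surface_dist(const NumericMatrix& a,
                                        const NumericMatrix& b,
                                        const NumericVector& spacing) {
  const int na = a.nrow(), nb = b.nrow();
  if (na == 0 || nb == 0) stop("empty boundary set");
  const double sr = spacing[0], sc = spacing[1];
  double sum_ab = 0.0, sum_ba = 0.0;
  std::vector<double> minb(nb, R_PosInf);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dr = (a(i, 0) - b(j, 0)) * sr;
      const double dc = (a(i, 1) - b(j, 1)) * sc;
      const double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
      if (d2 < minb[j]) minb[j] = d2;
    }
    sum_ab += std::sqrt(best);
  }
  for (int j = 0; j < nb; ++j) sum_ba += std::sqrt(minb[j]);
  return NumericVector::create(sum_ab / na, sum_ba / nb);
}
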