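#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fixed-radius neighbor label counts over a uniform bucket grid.
//
// out(i, k) = number of points j (self included) with integer label k+1 and
// (x_j - x_i)^2 + (y_j - y_i)^2 <= radius^2 (or < if strict). The squared-
// distance predicate is written identically to the pure-R oracle so both
// paths make bitwise-identical inclusion decisions.
//
// Bucket side length is max(radius, extent/256): a 3x3 bucket neighborhood
// then always covers the ball of the query radius, and the grid never
// allocates more than ~65k buckets however small the radius.
// [[Rcpp::export]]
IntegerMatrix label_counts_within(NumericVector x, NumericVector y,
                                  IntegerVector label, int n_labels,
                                  double radius, bool strict) {
  const int n = x.size();
  IntegerMatrix out(n, n_labels);
  if (n == 0) return out;
  const double r2 = radius * radius;

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double extent = std::max(xmax - xmin, ymax - ymin);
  double side = std::max(radius, extent / 256.0);
  if (side <= 0) side = 1.0;

  std::vector<int> bx(n), by(n);
  int nbx = 1, nby = 1;
  for (int i = 0; i < n; ++i) {
    bx[i] = (int)std::floor((x[i] - xmin) / side);
    by[i] = (int)std::floor((y[i] - ymin) / side);
    nbx = std::max(nbx, bx[i] + 1);
    nby = std::max(nby, by[i] + 1);
  }

  // counting sort of points into buckets (CSR layout)
  std::vector<int> head((size_t)nbx * nby + 1, 0);
  for (int i = 0; i < n; ++i) ++head[(size_t)by[i] * nbx + bx[i] + 1];
  for (size_t b = 1; b < head.size(); ++b) head[b] += head[b - 1];
  std::vector<int> order(n), pos(head.begin(), head.end() - 1);
  for (int i = 0; i < n; ++i) order[pos[(size_t)by[i] * nbx + bx[i]]++] = i;

  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int dby = -1; dby <= 1; ++dby) {
      int gy = by[i] + dby;
      if (gy < 0 || gy >= nby) continue;
      for (int dbx = -1; dbx <= 1; ++dbx) {
        int gx = bx[i] + dbx;
        if (gx < 0 || gx >= nbx) continue;
        size_t b = (size_t)gy * nbx + gx;
        for (int p = head[b]; p < head[b + 1]; ++p) {
          int j = order[p];
          double dx = x[j] - xi, dy = y[j] - yi;
          double d2 = dx * dx + dy * dy;
          if (strict ? (d2 < r2) : (d2 <= r2)) ++out(i, label[j] - 1);
        }
      }
    }
  }
  return out;
}
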