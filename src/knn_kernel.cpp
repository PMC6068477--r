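#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Per-pixel K-nearest-neighbor search in the (intensity, lambda*row,
// lambda*col) feature space. Pixels are scanned row-major; candidate set is
// either the whole image or a row band of `wsize` rows centred on the query
// pixel (half above, half below, clamped at the borders). Two selection
// strategies are provided:
//   0 = bounded insert: a K-slot array initialised with +Inf sentinels; a
//       candidate whose distance is <= the last slot replaces it and is
//       slid to its sorted position (insertion step of a shell-type sort).
//   1 = full sort: all candidate distances are collected and the first K in
//       ascending (distance, linear index) order are selected; this is the
//       canonical order a stable merge sort over the row-major scan yields.
// Linear pixel indices in the output are 0-based row-major (r * cols + c).

static inline double feat_dist(double di, double dr, double dc, int metric) {
  if (metric == 0) return std::sqrt(di * di + dr * dr + dc * dc);
  return std::fabs(di) + std::fabs(dr) + std::fabs(dc);
}

// [[Rcpp::export(name = ".knn_search_impl")]]
List knn_search_impl(NumericMatrix img, double lambda, int k, int wsize,
                     int metric, bool normalized_coords, bool include_self,
                     int strategy) {
  const int rows = img.nrow(), cols = img.ncol();
  const double n_d = (double)rows * (double)cols;
  if (n_d > 2147483647.0) stop("image too large for 32-bit pixel indices");
  const int n = rows * cols;
  const bool full = (wsize <= 0);
  const int half = full ? rows : wsize / 2;

  // smallest window over all pixels occurs at the first row
  const int min_rows = full ? rows : std::min(half, rows);
  const int min_cand = min_rows * cols - (include_self ? 0 : 1);
  if (min_cand < k)
    stop("smallest search window holds %d candidate pixels but k = %d; "
         "increase wsize or decrease k",
         min_cand, k);

  const double rscale =
      lambda * (normalized_coords ? (rows > 1 ? 1.0 / (rows - 1) : 0.0) : 1.0);
  const double cscale =
      lambda * (normalized_coords ? (cols > 1 ? 1.0 / (cols - 1) : 0.0) : 1.0);

  NumericMatrix out_d(k, n);
  IntegerMatrix out_i(k, n);
  double n_distances = 0.0;

  // row-major copy of the image: the candidate scan walks columns within a
  // row, which in R's column-major layout strides by `rows` and thrashes
  // the cache; contiguous row-major access keeps the inner loop streaming
  std::vector<double> im((size_t)n);
  for (int i = 0; i < rows; ++i)
    for (int j = 0; j < cols; ++j) im[(size_t)i * cols + j] = img(i, j);

  std::vector<double> nd((size_t)k);
  std::vector<int> ni((size_t)k);
  std::vector<std::pair<double, int> > cand;
  if (strategy == 1) cand.reserve((size_t)std::min(rows, full ? rows : wsize) * cols);

  for (int r = 0; r < rows; ++r) {
    Rcpp::checkUserInterrupt();
    const int lo = full ? 0 : std::max(0, r - half);
    const int hi = full ? rows - 1 : std::min(rows - 1, r + half - 1);
    for (int c = 0; c < cols; ++c) {
      const int self = r * cols + c;
      const double iv = im[(size_t)self];

      if (strategy == 0) {
        std::fill(nd.begin(), nd.end(), R_PosInf);
        std::fill(ni.begin(), ni.end(), NA_INTEGER);
        for (int i = lo; i <= hi; ++i) {
          const double dr = rscale * (double)(r - i);
          for (int j = 0; j < cols; ++j) {
            const int idx = i * cols + j;
            if (!include_self && idx == self) continue;
            const double d =
                feat_dist(iv - im[(size_t)idx], dr, cscale * (double)(c - j), metric);
            n_distances += 1.0;
            if (d <= nd[(size_t)k - 1]) {
              nd[(size_t)k - 1] = d;
              ni[(size_t)k - 1] = idx;
              for (int p = k - 1; p > 0 && nd[(size_t)p] < nd[(size_t)p - 1]; --p) {
                std::swap(nd[(size_t)p], nd[(size_t)p - 1]);
                std::swap(ni[(size_t)p], ni[(size_t)p - 1]);
              }
            }
          }
        }
        for (int p = 0; p < k; ++p) {
          out_d(p, self) = nd[(size_t)p];
          out_i(p, self) = ni[(size_t)p];
        }
      } else {
        cand.clear();
        for (int i = lo; i <= hi; ++i) {
          const double dr = rscale * (double)(r - i);
          for (int j = 0; j < cols; ++j) {
            const int idx = i * cols + j;
            if (!include_self && idx == self) continue;
            const double d =
                feat_dist(iv - im[(size_t)idx], dr, cscale * (double)(c - j), metric);
            n_distances += 1.0;
            cand.push_back(std::make_pair(d, idx));
          }
        }
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
        for (int p = 0; p < k; ++p) {
          out_d(p, self) = cand[(size_t)p].first;
          out_i(p, self) = cand[(size_t)p].second;
        }
      }
    }
  }

  return List::create(Named("distances") = out_d, Named("indices") = out_i,
                      Named("n_distances") = n_distances);
}
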