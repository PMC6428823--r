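#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical mask by breadth-first search.
// connectivity: 4 or 8. Returns an integer matrix, 0 for background,
// 1..n_components for foreground, labels assigned in raster-scan order.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity == 4 ? 4 : 8;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
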