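#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin kernel SVM trained by sequential minimal optimization.
//
// Solves the dual
//   max  sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j)
//   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
// with Platt's pairwise coordinate ascent: pick a KKT-violating example,
// pair it with a second one, solve the two-variable subproblem in closed
// form.  Randomized sweeps use R's RNG so results are reproducible under
// set.seed().  K is the precomputed kernel matrix (n x n); the R wrapper
// chooses the kernel and owns feature standardization.
// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_passes = 20,
               int max_iter = 20000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), err(n, 0.0);
  double b = 0.0;

  // f(i) - y_i with all alpha zero is just -y_i
  for (int i = 0; i < n; ++i) err[i] = -y[i];

  auto update_pair = [&](int i, int j) -> bool {
    if (i == j) return false;
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (L >= H) return false;
    double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    if (eta >= -1e-12) return false;
    double aj = aj_old - y[j] * (err[i] - err[j]) / eta;
    aj = std::min(H, std::max(L, aj));
    if (std::fabs(aj - aj_old) < 1e-7 * (aj + aj_old + 1e-7)) return false;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);

    double b1 = b - err[i] - y[i] * (ai - ai_old) * K(i, i)
                - y[j] * (aj - aj_old) * K(i, j);
    double b2 = b - err[j] - y[i] * (ai - ai_old) * K(i, j)
                - y[j] * (aj - aj_old) * K(j, j);
    double b_new;
    if (ai > 0 && ai < C) b_new = b1;
    else if (aj > 0 && aj < C) b_new = b2;
    else b_new = 0.5 * (b1 + b2);

    double di = y[i] * (ai - ai_old), dj = y[j] * (aj - aj_old);
    for (int k = 0; k < n; ++k) {
      err[k] += di * K(i, k) + dj * K(j, k) + (b_new - b);
    }
    alpha[i] = ai;
    alpha[j] = aj;
    b = b_new;
    return true;
  };

  int passes = 0, iter = 0;
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double r = err[i] * y[i];
      if ((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0)) {
        // second choice: maximize |E_i - E_j| over non-bound alphas,
        // falling back to a random partner
        int j = -1;
        double best = -1.0;
        for (int k = 0; k < n; ++k) {
          if (k == i) continue;
          if (alpha[k] > 0 && alpha[k] < C) {
            double gap = std::fabs(err[i] - err[k]);
            if (gap > best) { best = gap; j = k; }
          }
        }
        bool ok = (j >= 0) && update_pair(i, j);
        if (!ok) {
          int start = (int)std::floor(unif_rand() * n);
          for (int k = 0; k < n && !ok; ++k) {
            int cand = (start + k) % n;
            if (cand != i) ok = update_pair(i, cand);
          }
        }
        if (ok) ++changed;
      }
      ++iter;
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["iterations"] = iter);
}
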