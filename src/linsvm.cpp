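#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM with the
// shrinking heuristic (Hsieh et al. 2008, Algorithm 3; liblinear's
// L2R_L1LOSS_SVC_DUAL).  The bias is an augmented constant feature of
// value `bias`, i.e. the primal objective is
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i (w'x_i + b*bias))
// with b regularized like any other coordinate.  Per-sample costs C_i
// carry the class-balancing weights.  Samples are the columns of Xt
// (features x samples) so inner products run over contiguous memory.
// The coordinate order is shuffled with a fixed linear-congruential
// stream: results are bit-for-bit reproducible across runs/platforms.

static inline uint64_t lcg_next(uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return s >> 33;
}

// [[Rcpp::export(name = ".linsvm_fit_cpp")]]
List linsvm_fit_cpp(NumericMatrix Xt, IntegerVector y, NumericVector Ci,
                    double bias, double tol, int max_iter) {
  const int p = Xt.nrow(), n = Xt.ncol();
  const double *X = REAL(Xt);
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> w(p + 1, 0.0), alpha(n, 0.0), qd(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * p;
    double s = bias * bias;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qd[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  uint64_t rng = 88172645463325252ULL;
  int active = n, iter = 0;
  double pgmax_old = inf, pgmin_old = -inf;
  for (; iter < max_iter; ++iter) {
    double pgmax_new = -inf, pgmin_new = inf;
    for (int i = active - 1; i > 0; --i) {  // Fisher-Yates on the active set
      int j = (int)(lcg_next(rng) % (uint64_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (int k = 0; k < active; ++k) {
      const int i = idx[k];
      const double *xi = X + (size_t)i * p;
      double g = bias * w[p];
      for (int j = 0; j < p; ++j) g += xi[j] * w[j];
      g = y[i] * g - 1.0;                    // gradient of dual coord i
      double pg = 0.0;
      if (alpha[i] <= 0.0) {
        if (g > pgmax_old) {                 // shrink this coordinate
          --active; std::swap(idx[k], idx[active]); --k; continue;
        }
        if (g < 0.0) pg = g;
      } else if (alpha[i] >= Ci[i]) {
        if (g < pgmin_old) {
          --active; std::swap(idx[k], idx[active]); --k; continue;
        }
        if (g > 0.0) pg = g;
      } else {
        pg = g;
      }
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qd[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > Ci[i]) a_new = Ci[i];
        alpha[i] = a_new;
        double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          w[p] += d * bias;
        }
      }
    }
    if (pgmax_new - pgmin_new <= tol) {
      if (active == n) { ++iter; break; }
      // optimal on the active set: recheck all coordinates once
      active = n; pgmax_old = inf; pgmin_old = -inf;
      continue;
    }
    pgmax_old = (pgmax_new <= 0.0) ? inf : pgmax_new;
    pgmin_old = (pgmin_new >= 0.0) ? -inf : pgmin_new;
  }
  NumericVector wout(p);
  for (int j = 0; j < p; ++j) wout[j] = w[j];
  return List::create(_["w"] = wout, _["b"] = w[p] * bias,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["n_iter"] = iter);
}
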