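#include "svm.h"
#include "rng.h"
#include <cmath>
#include <algorithm>

// Dual coordinate descent for
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x~_i),   x~_i = (x_i, B)
// alpha_i in [0, C]; deterministic permuted update order; convergence on the
// maximum projected-gradient violation per epoch (liblinear-style). The bias
// enters as a scaled constant input (B = 10) so its regularization is mild
// and solutions track the equality-constrained-bias formulation closely.
std::vector<double> svm_train_linear(const std::vector<double> &Xr,
                                     const std::vector<int> &y, int n, int p,
                                     double cost, int max_epochs, double tol) {
  const double B = SVM_BIAS_SCALE;
  const int pa = p + 1; // augmented with the bias input
  std::vector<double> w(pa, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    const double *x = Xr.data() + static_cast<size_t>(i) * p;
    double q = B * B;
    for (int j = 0; j < p; ++j) q += x[j] * x[j];
    qii[i] = q;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  XRng rng(90001);
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    rng.shuffle(order);
    double max_viol = 0.0;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      const double *x = Xr.data() + static_cast<size_t>(i) * p;
      double wx = w[p] * B;
      for (int j = 0; j < p; ++j) wx += w[j] * x[j];
      double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= cost && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qii[i], 0.0), cost);
        if (a_new != a_old) {
          double d = (a_new - a_old) * y[i];
          for (int j = 0; j < p; ++j) w[j] += d * x[j];
          w[p] += d * B;
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  w[p] *= B; // report the effective intercept
  return w;
}

double svm_decision(const std::vector<double> &w, const double *x, int p) {
  double v = w[p];
  for (int j = 0; j < p; ++j) v += w[j] * x[j];
  return v;
}

// Same dual problem solved on a precomputed Gram matrix K (which already
// carries the +1 of the bias feature). Decision values s_i = sum_j a_j y_j
// K_ij are maintained incrementally (O(n) per update), so one shared Gram
// serves every leave-one-out fold: training skips the held-out index and
// s[hold] is the held-out decision value at the end.
void svm_gram_solve(const std::vector<double> &K, const std::vector<int> &y,
                    int n, int hold, double cost, int max_epochs, double tol,
                    std::vector<double> &alpha, std::vector<double> &s) {
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i != hold) order.push_back(i);
  XRng rng(90001u + static_cast<uint64_t>(hold + 1));
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    rng.shuffle(order);
    double max_viol = 0.0;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int i = order[oi];
      double g = y[i] * s[i] - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= cost && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / K[static_cast<size_t>(i) * n + i], 0.0), cost);
        if (a_new != a_old) {
          double d = (a_new - a_old) * y[i];
          const double *Ki = K.data() + static_cast<size_t>(i) * n;
          for (int l = 0; l < n; ++l) s[l] += d * Ki[l];
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
}

double svm_loocv_gram_one(const std::vector<double> &K,
                          const std::vector<int> &y, int n, int hold,
                          double cost, int max_epochs, double tol) {
  std::vector<double> alpha(n, 0.0), s(n, 0.0);
  svm_gram_solve(K, y, n, hold, cost, max_epochs, tol, alpha, s);
  return s[hold];
}

// all leave-one-out decision values, warm-starting every fold from the
// full-sample dual solution (folds differ by one subject, so a handful of
// refinement epochs reaches the fold optimum)
void svm_loocv_gram_all(const std::vector<double> &K,
                        const std::vector<int> &y, int n, double cost,
                        std::vector<double> &decision, int max_epochs,
                        double tol) {
  std::vector<double> alpha0(n, 0.0), s0(n, 0.0);
  svm_gram_solve(K, y, n, -1, cost, max_epochs, tol, alpha0, s0);
  decision.resize(n);
  std::vector<double> alpha(n), s(n);
  for (int m = 0; m < n; ++m) {
    alpha = alpha0;
    s = s0;
    if (alpha[m] != 0.0) {
      double d = -alpha[m] * y[m];
      const double *Km = K.data() + static_cast<size_t>(m) * n;
      for (int l = 0; l < n; ++l) s[l] += d * Km[l];
      alpha[m] = 0.0;
    }
    // warm-started refinement needs only a few passes
    svm_gram_solve(K, y, n, m, cost, std::min(max_epochs, 50), tol, alpha, s);
    decision[m] = s[m];
  }
}

// Gram of the selected feature columns (col-major X), plus B^2 for the bias
void build_gram(const double *X, int n, const int *sel, int nsel,
                std::vector<double> &K) {
  K.assign(static_cast<size_t>(n) * n, SVM_BIAS_SCALE * SVM_BIAS_SCALE);
  for (int jj = 0; jj < nsel; ++jj) {
    const double *col = X + static_cast<size_t>(sel[jj]) * n;
    for (int i = 0; i < n; ++i) {
      double xi = col[i];
      if (xi == 0.0) continue;
      double *Ki = K.data() + static_cast<size_t>(i) * n;
      for (int l = i; l < n; ++l) Ki[l] += xi * col[l];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < i; ++l)
      K[static_cast<size_t>(i) * n + l] = K[static_cast<size_t>(l) * n + i];
}
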