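#include <Rcpp.h>
#include <cmath>
#include "kendall.h"
using namespace Rcpp;

// Tau-b between a feature and binary labels by direct pair enumeration,
// tie-corrected in both variables:
//   tau_b = S / sqrt((N - Tx)(N - Ty)),  S = sum_{i<l} sgn(x_i-x_l) sgn(y_i-y_l)
// The per-subject concordance sums c_m and tie counts t_m let the leave-one-out
// fold values be recovered without re-enumerating pairs:
//   S_m = S - c_m,  Tx_m = Tx - tx_m,  Ty_m = Ty - ty_m,  N' = (n-1)(n-2)/2.
void kendall_powers_core(const double *X, const int *y, int n, int p,
                         double *powers_out, double *fold_out) {
  const double N = n * (n - 1) / 2.0;
  const double Nf = (n - 1) * (n - 2) / 2.0;

  std::vector<double> cm(n), ty(n);
  std::vector<double> tx(n);

  double Ty = 0.0;
  for (int m = 0; m < n; ++m) {
    int same = 0;
    for (int l = 0; l < n; ++l)
      if (l != m && y[l] == y[m]) ++same;
    ty[m] = same;
    Ty += same;
  }
  Ty /= 2.0;

  for (int j = 0; j < p; ++j) {
    const double *x = X + static_cast<size_t>(j) * n;
    double S = 0.0, Tx = 0.0;
    std::fill(cm.begin(), cm.end(), 0.0);
    std::fill(tx.begin(), tx.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = i + 1; l < n; ++l) {
        double dx = x[i] - x[l];
        int dy = y[i] - y[l];
        if (dx == 0.0) {
          Tx += 1.0;
          tx[i] += 1.0;
          tx[l] += 1.0;
        } else if (dy != 0) {
          double s = (dx > 0.0) == (dy > 0) ? 1.0 : -1.0;
          S += s;
          cm[i] += s;
          cm[l] += s;
        }
      }
    }
    double den = (N - Tx) * (N - Ty);
    powers_out[j] = den > 0.0 ? std::fabs(S / std::sqrt(den)) : 0.0;
    if (fold_out) {
      for (int m = 0; m < n; ++m) {
        double denf = (Nf - (Tx - tx[m])) * (Nf - (Ty - ty[m]));
        double v = denf > 0.0 ? std::fabs((S - cm[m]) / std::sqrt(denf)) : 0.0;
        fold_out[static_cast<size_t>(m) * p + j] = v;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_kendall_powers(const NumericMatrix &X, const IntegerVector &y) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  kendall_powers_core(X.begin(), y.begin(), n, p, out.begin(), nullptr);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_fold_kendall_powers(const NumericMatrix &X, const IntegerVector &y) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> powers(p);
  NumericMatrix folds(p, n);
  kendall_powers_core(X.begin(), y.begin(), n, p, powers.data(), folds.begin());
  return folds;
}
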