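#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include "kendall.h"
#include "svm.h"
#include "rng.h"
using namespace Rcpp;

// indices (0-based) of the k largest powers, ordered by power descending with
// ascending-index tie-break
static void top_k(const double *powers, int p, int k, std::vector<int> &out) {
  out.resize(p);
  for (int j = 0; j < p; ++j) out[j] = j;
  auto cmp = [powers](int a, int b) {
    if (powers[a] != powers[b]) return powers[a] > powers[b];
    return a < b;
  };
  if (k < p) {
    std::nth_element(out.begin(), out.begin() + k, out.end(), cmp);
    out.resize(k);
  }
  std::sort(out.begin(), out.end(), cmp);
}

// [[Rcpp::export]]
List cpp_svm_train(const NumericMatrix &X, const IntegerVector &y, double cost) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> Xr(static_cast<size_t>(n) * p);
  std::vector<int> ypm(n);
  for (int i = 0; i < n; ++i) {
    ypm[i] = y[i] == 1 ? 1 : -1;
    for (int j = 0; j < p; ++j) Xr[static_cast<size_t>(i) * p + j] = X(i, j);
  }
  std::vector<double> w = svm_train_linear(Xr, ypm, n, p, cost, 2000, 1e-4);
  NumericVector wv(p);
  for (int j = 0; j < p; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[p]);
}

// leave-one-out predictions for a fixed feature set via the shared Gram;
// labels in {0,1}; decision value exactly 0 resolves to label 0
static void loocv_predict_gram(const std::vector<double> &K,
                               const std::vector<int> &ypm, int n, double cost,
                               int *pred) {
  std::vector<double> dec;
  svm_loocv_gram_all(K, ypm, n, cost, dec);
  for (int m = 0; m < n; ++m) pred[m] = dec[m] > 0.0 ? 1 : 0;
}

static void to_pm(const int *y, int n, std::vector<int> &ypm) {
  ypm.resize(n);
  for (int i = 0; i < n; ++i) ypm[i] = y[i] == 1 ? 1 : -1;
}

static void accuracy_from_pred(const int *y, const int *pred, int n,
                               double *acc, double *sens, double *spec) {
  int n0 = 0, n1 = 0, c0 = 0, c1 = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] == 0) { ++n0; if (pred[i] == 0) ++c0; }
    else           { ++n1; if (pred[i] == 1) ++c1; }
  }
  *spec = n0 > 0 ? static_cast<double>(c0) / n0 : NA_REAL;
  *sens = n1 > 0 ? static_cast<double>(c1) / n1 : NA_REAL;
  *acc = 0.5 * (*spec + *sens);
}

// [[Rcpp::export]]
IntegerVector cpp_svm_loocv(const NumericMatrix &X, const IntegerVector &y, double cost) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> sel(p);
  for (int j = 0; j < p; ++j) sel[j] = j;
  std::vector<double> K;
  build_gram(X.begin(), n, sel.data(), p, K);
  std::vector<int> ypm;
  to_pm(y.begin(), n, ypm);
  IntegerVector pred(n);
  loocv_predict_gram(K, ypm, n, cost, pred.begin());
  return pred;
}

// [[Rcpp::export]]
IntegerMatrix cpp_fold_topk(const NumericMatrix &X, const IntegerVector &y, int k) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> folds(static_cast<size_t>(p) * n), powers(p);
  kendall_powers_core(X.begin(), y.begin(), n, p, powers.data(), folds.data());
  IntegerMatrix out(k, n);
  std::vector<int> idx;
  for (int m = 0; m < n; ++m) {
    top_k(folds.data() + static_cast<size_t>(m) * p, p, k, idx);
    for (int r = 0; r < k; ++r) out(r, m) = idx[r] + 1;
  }
  return out;
}

// full pipeline on one label vector: per-fold tau-b ranking -> top-k ->
// consensus (features in every fold's top-k) -> LOOCV linear SVM on the
// fixed consensus set
static void nested_accuracy(const double *X, int n, int p, const int *y, int k,
                            double cost, double *acc, double *sens, double *spec,
                            bool *empty, std::vector<int> *consensus_out,
                            std::vector<int> *pred_out,
                            std::vector<double> &fold_buf,
                            std::vector<double> &power_buf,
                            std::vector<double> &gram_buf) {
  kendall_powers_core(X, y, n, p, power_buf.data(), fold_buf.data());
  std::vector<int> cnt(p, 0), idx;
  for (int m = 0; m < n; ++m) {
    top_k(fold_buf.data() + static_cast<size_t>(m) * p, p, k, idx);
    for (int r = 0; r < k; ++r) ++cnt[idx[r]];
  }
  std::vector<int> cons;
  for (int j = 0; j < p; ++j)
    if (cnt[j] == n) cons.push_back(j);
  if (consensus_out) *consensus_out = cons;
  if (cons.empty()) {
    *empty = true;
    *acc = 0.5; *sens = 0.5; *spec = 0.5;
    return;
  }
  *empty = false;
  build_gram(X, n, cons.data(), static_cast<int>(cons.size()), gram_buf);
  std::vector<int> ypm;
  to_pm(y, n, ypm);
  std::vector<int> pred(n);
  loocv_predict_gram(gram_buf, ypm, n, cost, pred.data());
  if (pred_out) *pred_out = pred;
  accuracy_from_pred(y, pred.data(), n, acc, sens, spec);
}

// [[Rcpp::export]]
List cpp_nested_classify(const NumericMatrix &X, const IntegerVector &y, int k,
                         double cost) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> fold_buf(static_cast<size_t>(p) * n), power_buf(p), gram_buf;
  double acc, sens, spec;
  bool empty;
  std::vector<int> cons, pred;
  nested_accuracy(X.begin(), n, p, y.begin(), k, cost, &acc, &sens, &spec,
                  &empty, &cons, &pred, fold_buf, power_buf, gram_buf);
  IntegerVector consv(cons.size());
  for (size_t j = 0; j < cons.size(); ++j) consv[j] = cons[j] + 1;
  IntegerVector predv(empty ? 0 : n);
  if (!empty) for (int i = 0; i < n; ++i) predv[i] = pred[i];
  return List::create(_["overall_accuracy"] = acc, _["sensitivity"] = sens,
                      _["specificity"] = spec, _["consensus"] = consv,
                      _["predictions"] = predv, _["empty_consensus"] = empty);
}

// honest nested LOOCV: every fold's SVM is restricted to that fold's own
// training-only top-k ranking (no consensus intersection), so the held-out
// subject's label never reaches its feature selection through other folds
// [[Rcpp::export]]
List cpp_honest_loocv(const NumericMatrix &X, const IntegerVector &y, int k,
                      double cost) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> folds(static_cast<size_t>(p) * n), powers(p);
  kendall_powers_core(X.begin(), y.begin(), n, p, powers.data(), folds.data());
  std::vector<int> ypm;
  to_pm(y.begin(), n, ypm);
  IntegerVector pred(n);
  std::vector<int> idx;
  std::vector<double> K;
  for (int m = 0; m < n; ++m) {
    top_k(folds.data() + static_cast<size_t>(m) * p, p, k, idx);
    std::sort(idx.begin(), idx.end());
    build_gram(X.begin(), n, idx.data(), static_cast<int>(idx.size()), K);
    pred[m] = svm_loocv_gram_one(K, ypm, n, m, cost) > 0.0 ? 1 : 0;
  }
  double acc, sens, spec;
  accuracy_from_pred(y.begin(), pred.begin(), n, &acc, &sens, &spec);
  return List::create(_["overall_accuracy"] = acc, _["sensitivity"] = sens,
                      _["specificity"] = spec, _["predictions"] = pred);
}

// permutation null of the overall accuracy. nested = TRUE reruns the whole
// selection-within-folds pipeline per permutation; nested = FALSE keeps the
// supplied consensus feature set fixed and only refits the LOOCV SVMs.
// [[Rcpp::export]]
List cpp_permutation_null(const NumericMatrix &X, const IntegerVector &y, int k,
                          double cost, int n_perm, double seed, bool nested,
                          const IntegerVector &consensus) {
  int n = X.nrow(), p = X.ncol();
  XRng rng(static_cast<uint64_t>(seed));
  std::vector<int> yp(y.begin(), y.end());
  NumericVector acc(n_perm);
  int n_empty = 0;
  std::vector<double> fold_buf(static_cast<size_t>(p) * n), power_buf(p), gram_buf;

  std::vector<double> Kfixed;
  if (!nested && consensus.size() > 0) {
    std::vector<int> sel(consensus.size());
    for (int j = 0; j < consensus.size(); ++j) sel[j] = consensus[j] - 1;
    build_gram(X.begin(), n, sel.data(), static_cast<int>(sel.size()), Kfixed);
  }

  for (int b = 0; b < n_perm; ++b) {
    rng.shuffle(yp);
    double a, se, sp;
    if (nested) {
      bool empty = false;
      nested_accuracy(X.begin(), n, p, yp.data(), k, cost, &a, &se, &sp,
                      &empty, nullptr, nullptr, fold_buf, power_buf, gram_buf);
      if (empty) ++n_empty;
    } else {
      std::vector<int> ypm;
      to_pm(yp.data(), n, ypm);
      std::vector<int> pred(n);
      loocv_predict_gram(Kfixed, ypm, n, cost, pred.data());
      accuracy_from_pred(yp.data(), pred.data(), n, &a, &se, &sp);
    }
    acc[b] = a;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["null_accuracy"] = acc, _["n_empty_consensus"] = n_empty);
}
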