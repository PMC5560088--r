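#pragma once
#include <vector>

// constant input carrying the intercept (liblinear's -B); large enough that
// the intercept is only mildly regularized
#define SVM_BIAS_SCALE 10.0

// Linear soft-margin SVM trained in the dual by coordinate descent
// (L1 hinge loss, the same objective libsvm solves with a linear kernel);
// the bias is folded in as a constant input feature.
// Xr: row-major n x p training matrix, y in {-1,+1}.
// Returns w of length p + 1 (last entry = bias).
std::vector<double> svm_train_linear(const std::vector<double> &Xr,
                                     const std::vector<int> &y, int n, int p,
                                     double cost, int max_epochs = 2000,
                                     double tol = 1e-4);

// decision value for one sample (length-p feature row)
double svm_decision(const std::vector<double> &w, const double *x, int p);

// Gram-based dual coordinate descent; `hold` (-1 for none) is excluded from
// the updates. alpha and s (decision values, consistent with alpha) are
// updated in place, enabling warm starts.
void svm_gram_solve(const std::vector<double> &K, const std::vector<int> &y,
                    int n, int hold, double cost, int max_epochs, double tol,
                    std::vector<double> &alpha, std::vector<double> &s);

// Gram-based leave-one-out fold: trains on all indices except `hold` using
// the shared Gram K (bias included) and returns the held-out decision value.
double svm_loocv_gram_one(const std::vector<double> &K,
                          const std::vector<int> &y, int n, int hold,
                          double cost, int max_epochs = 150, double tol = 0.01);

// all leave-one-out decision values with warm starts from the full solution
void svm_loocv_gram_all(const std::vector<double> &K,
                        const std::vector<int> &y, int n, double cost,
                        std::vector<double> &decision, int max_epochs = 150,
                        double tol = 0.01);

// Gram of selected feature columns (X col-major, n rows) plus the bias term
void build_gram(const double *X, int n, const int *sel, int nsel,
                std::vector<double> &K);
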