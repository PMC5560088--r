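#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// weighted Newman modularity of a hard partition:
//   Q = sum_c [ W_c / 2m - (k_c / 2m)^2 ]
// with W_c the total (ordered-pair) weight inside community c and k_c the
// summed strengths; equals (1/2m) sum_ij (w_ij - k_i k_j / 2m) delta(c_i,c_j)
static double modularity_value(const std::vector<double> &W, int n,
                               const std::vector<int> &comm) {
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, comm[i] + 1);
  std::vector<double> within(nc, 0.0), ktot(nc, 0.0);
  double m2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double k = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = W[static_cast<size_t>(j) * n + i];
      k += w;
      if (comm[i] == comm[j]) within[comm[i]] += w;
    }
    ktot[comm[i]] += k;
    m2 += k;
  }
  if (m2 <= 0.0) return 0.0;
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += within[c] / m2 - (ktot[c] / m2) * (ktot[c] / m2);
  return q;
}

// [[Rcpp::export]]
double cpp_modularity_q(const NumericMatrix &W, const IntegerVector &membership) {
  int n = W.nrow();
  std::vector<double> Wv(W.begin(), W.end());
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = membership[i] - 1;
  return modularity_value(Wv, n, comm);
}

// one pass of greedy local moves on the (possibly aggregated) graph M;
// M carries self-loops on the diagonal as ordered-pair weight (2x the summed
// internal edge weight). Returns true if any node changed community.
static bool one_level(const std::vector<double> &M, int n, double m2,
                      std::vector<int> &comm, XRng &rng) {
  std::vector<double> k(n, 0.0), tot(n, 0.0), wcomm(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += M[static_cast<size_t>(j) * n + i];
  for (int i = 0; i < n; ++i) tot[comm[i]] += k[i];
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  rng.shuffle(order);

  bool improved = false, moved = true;
  std::vector<int> touched;
  while (moved) {
    moved = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int c_old = comm[i];
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double w = M[static_cast<size_t>(j) * n + i];
        if (w > 0.0) {
          int c = comm[j];
          if (wcomm[c] == 0.0) touched.push_back(c);
          wcomm[c] += w;
        }
      }
      if (wcomm[c_old] == 0.0) touched.push_back(c_old);
      tot[c_old] -= k[i];
      double best_gain = wcomm[c_old] - k[i] * tot[c_old] / m2;
      int best = c_old;
      for (int t = 0; t < static_cast<int>(touched.size()); ++t) {
        int c = touched[t];
        if (c == c_old) continue;
        double gain = wcomm[c] - k[i] * tot[c] / m2;
        if (gain > best_gain + 1e-12) { best_gain = gain; best = c; }
      }
      tot[best] += k[i];
      comm[i] = best;
      if (best != c_old) { moved = true; improved = true; }
      for (int t = 0; t < static_cast<int>(touched.size()); ++t)
        wcomm[touched[t]] = 0.0;
    }
  }
  return improved;
}

// multi-level (Louvain-style) modularity optimization with seeded random
// node orders; restart-based, best-Q partition wins, ties to the first found
// [[Rcpp::export]]
List cpp_louvain(const NumericMatrix &W, int n_runs, double seed) {
  int n0 = W.nrow();
  std::vector<double> W0(W.begin(), W.end());
  double m2 = 0.0;
  for (size_t t = 0; t < W0.size(); ++t) m2 += W0[t];

  std::vector<int> best_comm(n0);
  for (int i = 0; i < n0; ++i) best_comm[i] = i;
  double best_q = modularity_value(W0, n0, best_comm);

  for (int run = 0; run < n_runs; ++run) {
    XRng rng(derive_seed(static_cast<uint64_t>(seed), static_cast<uint64_t>(run)));
    std::vector<double> M = W0;
    int n = n0;
    std::vector<int> assign(n0); // node of original graph -> community at current level
    for (int i = 0; i < n0; ++i) assign[i] = i;

    for (;;) {
      std::vector<int> comm(n);
      for (int i = 0; i < n; ++i) comm[i] = i;
      bool improved = one_level(M, n, m2, comm, rng);
      // relabel consecutively
      std::vector<int> relab(n, -1);
      int nc = 0;
      for (int i = 0; i < n; ++i)
        if (relab[comm[i]] < 0) relab[comm[i]] = nc++;
      for (int i = 0; i < n; ++i) comm[i] = relab[comm[i]];
      for (int i = 0; i < n0; ++i) assign[i] = comm[assign[i]];
      if (!improved || nc == n) break;
      // aggregate
      std::vector<double> M2(static_cast<size_t>(nc) * nc, 0.0);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
          M2[static_cast<size_t>(comm[j]) * nc + comm[i]] +=
              M[static_cast<size_t>(j) * n + i];
      M.swap(M2);
      n = nc;
    }
    double q = modularity_value(W0, n0, assign);
    if (q > best_q + 1e-12) { best_q = q; best_comm = assign; }
  }

  // consecutive 1-based ids in order of first appearance
  std::vector<int> relab(n0, -1);
  int nc = 0;
  IntegerVector memb(n0);
  for (int i = 0; i < n0; ++i) {
    if (relab[best_comm[i]] < 0) relab[best_comm[i]] = ++nc;
    memb[i] = relab[best_comm[i]];
  }
  return List::create(_["membership"] = memb, _["q"] = best_q,
                      _["n_modules"] = nc);
}
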