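#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include "rng.h"
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// all-pairs shortest paths by Floyd-Warshall on a dense length matrix
// (lengths[i][j] = INF when no edge); n here is <= a few hundred
static void floyd_warshall(std::vector<double> &d, int n) {
  for (int k = 0; k < n; ++k) {
    const double *dk = d.data() + static_cast<size_t>(k) * n;
    for (int i = 0; i < n; ++i) {
      double dik = d[static_cast<size_t>(i) * n + k];
      if (dik == INF) continue;
      double *di = d.data() + static_cast<size_t>(i) * n;
      for (int j = 0; j < n; ++j) {
        double v = dik + dk[j];
        if (v < di[j]) di[j] = v;
      }
    }
  }
}

// mean over ordered node pairs of 1/d_ij with edge length 1/w; disconnected
// pairs contribute 0, so the measure is defined on fragmented graphs
static double global_eff_core(const double *W, int n, std::vector<double> &d) {
  if (n < 2) return 0.0;
  d.assign(static_cast<size_t>(n) * n, INF);
  for (int i = 0; i < n; ++i) {
    d[static_cast<size_t>(i) * n + i] = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = W[static_cast<size_t>(j) * n + i];
      if (i != j && w > 0.0) d[static_cast<size_t>(i) * n + j] = 1.0 / w;
    }
  }
  floyd_warshall(d, n);
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && d[static_cast<size_t>(i) * n + j] < INF)
        s += 1.0 / d[static_cast<size_t>(i) * n + j];
  return s / (static_cast<double>(n) * (n - 1));
}

// weighted local efficiency: per node, efficiency among its neighbours with
// the node removed; neighbour-subgraph path lengths are computed on
// cube-rooted inverse weights and each term is scaled by the cube roots of
// the two edges connecting the pair to the centre node:
//   E_loc(u) = sum_{j!=h in N(u)} (w_uj w_uh)^{1/3} / d_jh  /  (k_u (k_u-1)),
// with d_jh the shortest path among 1/w^{1/3} lengths on G[N(u)].
// Nodes with fewer than two neighbours contribute 0; the nodal mean is
// returned. cw holds the cube-rooted weights (0 where no edge).
static double local_eff_core(const double *cw, int n, std::vector<int> &nb,
                             std::vector<double> &d) {
  double total = 0.0;
  for (int u = 0; u < n; ++u) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != u && cw[static_cast<size_t>(j) * n + u] > 0.0) nb.push_back(j);
    int k = static_cast<int>(nb.size());
    if (k < 2) continue;
    d.assign(static_cast<size_t>(k) * k, INF);
    for (int a = 0; a < k; ++a) {
      d[static_cast<size_t>(a) * k + a] = 0.0;
      const double *col = cw + static_cast<size_t>(nb[a]) * n;
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        double c = col[nb[b]];
        if (c > 0.0) d[static_cast<size_t>(b) * k + a] = 1.0 / c;
      }
    }
    floyd_warshall(d, k);
    double num = 0.0;
    for (int a = 0; a < k; ++a) {
      double wua = cw[static_cast<size_t>(nb[a]) * n + u];
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        double dab = d[static_cast<size_t>(a) * k + b];
        if (dab == INF) continue;
        num += wua * cw[static_cast<size_t>(nb[b]) * n + u] / dab;
      }
    }
    total += num / (static_cast<double>(k) * (k - 1));
  }
  return total / n;
}

static void cbrt_matrix(const double *W, int n, std::vector<double> &cw) {
  cw.assign(static_cast<size_t>(n) * n, 0.0);
  for (size_t t = 0; t < cw.size(); ++t)
    if (W[t] > 0.0) cw[t] = std::cbrt(W[t]);
}

// [[Rcpp::export]]
double cpp_global_efficiency(const NumericMatrix &W) {
  std::vector<double> d;
  return global_eff_core(W.begin(), W.nrow(), d);
}

// [[Rcpp::export]]
double cpp_local_efficiency(const NumericMatrix &W) {
  int n = W.nrow();
  std::vector<double> cw, d;
  std::vector<int> nb;
  cbrt_matrix(W.begin(), n, cw);
  return local_eff_core(cw.data(), n, nb, d);
}

struct EdgeList {
  std::vector<int> a, b;          // endpoints
  std::vector<double> w;          // weights
};

static EdgeList matrix_edges(const double *W, int n) {
  EdgeList e;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = W[static_cast<size_t>(j) * n + i];
      if (w > 0.0) { e.a.push_back(i); e.b.push_back(j); e.w.push_back(w); }
    }
  return e;
}

// degree-preserving double-edge swaps (~swaps_per_edge attempts per edge) on
// the endpoint lists in place; adj is the boolean adjacency, updated.
// Returns the number of successful swaps.
static int rewire_edges(std::vector<int> &ea, std::vector<int> &eb, int n,
                        std::vector<char> &adj, XRng &rng, int swaps_per_edge) {
  int m = static_cast<int>(ea.size()), ok = 0;
  int attempts = swaps_per_edge * m;
  for (int t = 0; t < attempts && m >= 2; ++t) {
    int e1 = rng.below(m), e2 = rng.below(m);
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (rng.below(2)) std::swap(c, d); // random orientation
    // propose a-d, c-b
    if (a == d || c == b || a == c || b == d) continue;
    if (adj[static_cast<size_t>(a) * n + d] || adj[static_cast<size_t>(c) * n + b])
      continue;
    adj[static_cast<size_t>(a) * n + b] = adj[static_cast<size_t>(b) * n + a] = 0;
    adj[static_cast<size_t>(c) * n + d] = adj[static_cast<size_t>(d) * n + c] = 0;
    adj[static_cast<size_t>(a) * n + d] = adj[static_cast<size_t>(d) * n + a] = 1;
    adj[static_cast<size_t>(c) * n + b] = adj[static_cast<size_t>(b) * n + c] = 1;
    eb[e1] = d;
    ea[e2] = c; eb[e2] = b;
    ++ok;
  }
  return ok;
}

// one null network; idx selects the stream so that null i of a batch equals
// the i-th singly generated null for the same base seed
// [[Rcpp::export]]
List cpp_rewired_null(const NumericMatrix &W, double seed, int idx,
                      int swaps_per_edge) {
  int n = W.nrow();
  EdgeList e = matrix_edges(W.begin(), n);
  int m = static_cast<int>(e.a.size());
  std::vector<char> adj(static_cast<size_t>(n) * n, 0);
  for (int t = 0; t < m; ++t)
    adj[static_cast<size_t>(e.a[t]) * n + e.b[t]] =
        adj[static_cast<size_t>(e.b[t]) * n + e.a[t]] = 1;
  XRng rng(derive_seed(static_cast<uint64_t>(seed), static_cast<uint64_t>(idx)));
  int ok = rewire_edges(e.a, e.b, n, adj, rng, swaps_per_edge);
  std::vector<double> wshuf(e.w);
  rng.shuffle(wshuf);
  NumericMatrix M(n, n);
  for (int t = 0; t < m; ++t) {
    M(e.a[t], e.b[t]) = wshuf[t];
    M(e.b[t], e.a[t]) = wshuf[t];
  }
  return List::create(_["weights"] = M, _["n_swaps"] = ok);
}

// fused null loop: global and local efficiency of n_nulls rewired networks.
// Edge extraction, cube roots of the (invariant) weight multiset and all
// work buffers are shared across nulls.
// [[Rcpp::export]]
NumericMatrix cpp_null_efficiencies(const NumericMatrix &W, int n_nulls,
                                    double seed, int swaps_per_edge) {
  int n = W.nrow();
  EdgeList e0 = matrix_edges(W.begin(), n);
  int m = static_cast<int>(e0.a.size());
  std::vector<double> cw0(m);
  for (int t = 0; t < m; ++t) cw0[t] = std::cbrt(e0.w[t]);

  NumericMatrix out(n_nulls, 2);
  std::vector<int> ea, eb, perm(m), nb;
  std::vector<char> adj;
  std::vector<double> Wn, Cn, d;
  for (int i = 0; i < n_nulls; ++i) {
    XRng rng(derive_seed(static_cast<uint64_t>(seed), static_cast<uint64_t>(i)));
    ea = e0.a; eb = e0.b;
    adj.assign(static_cast<size_t>(n) * n, 0);
    for (int t = 0; t < m; ++t)
      adj[static_cast<size_t>(ea[t]) * n + eb[t]] =
          adj[static_cast<size_t>(eb[t]) * n + ea[t]] = 1;
    rewire_edges(ea, eb, n, adj, rng, swaps_per_edge);
    // deal the weight multiset (and its cube roots) onto the rewired edges
    // with the same permutation the single-null path applies to the weights
    for (int t = 0; t < m; ++t) perm[t] = t;
    rng.shuffle(perm);
    Wn.assign(static_cast<size_t>(n) * n, 0.0);
    Cn.assign(static_cast<size_t>(n) * n, 0.0);
    for (int t = 0; t < m; ++t) {
      size_t ij = static_cast<size_t>(ea[t]) * n + eb[t];
      size_t ji = static_cast<size_t>(eb[t]) * n + ea[t];
      Wn[ij] = Wn[ji] = e0.w[perm[t]];
      Cn[ij] = Cn[ji] = cw0[perm[t]];
    }
    out(i, 0) = global_eff_core(Wn.data(), n, d);
    out(i, 1) = local_eff_core(Cn.data(), n, nb, d);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
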