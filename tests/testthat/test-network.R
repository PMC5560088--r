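test_that("proportional thresholding keeps the exact edge budget", {
  set.seed(1)
  z <- matrix(rnorm(45 * 45, 0.2, 0.3), 45)
  z <- (z + t(z)) / 2; diag(z) <- 0
  g <- suppressMessages(proportional_threshold(z, 0.10))
  expect_equal(sum(g$weights[upper.tri(g$weights)] > 0), 99) # round(.10 * 990)
  expect_true(all(g$weights >= 0))
  # retained weights keep their values and are the largest positives
  kept <- g$weights[upper.tri(g$weights)]
  pos <- sort(pmax(z[upper.tri(z)], 0), decreasing = TRUE)
  expect_equal(sort(kept[kept > 0], decreasing = TRUE), pos[1:99])
  # sparsity 1 on an all-positive matrix only zeroes negatives
  zp <- abs(z); diag(zp) <- 0
  expect_equal(proportional_threshold(zp, 1)$weights, zp, ignore_attr = TRUE)
  # degenerate input: fewer positives than requested
  few <- matrix(0, 6, 6)
  few[1, 2] <- few[2, 3] <- few[3, 4] <- few[4, 5] <- few[5, 6] <- 0.5
  few <- few + t(few)
  expect_message(g5 <- proportional_threshold(few, 10 / 15), "achieved sparsity")
  expect_equal(sum(g5$weights[upper.tri(g5$weights)] > 0), 5)
})

test_that("global efficiency matches definitions and brute force", {
  # complete unit-weight graph: every pair at distance 1
  K <- matrix(1, 5, 5); diag(K) <- 0
  expect_equal(global_efficiency(weighted_graph(K)), 1)
  # fully disconnected
  expect_equal(global_efficiency(weighted_graph(matrix(0, 2, 2))), 0)
  # 5-node weighted path graph against the Floyd-Warshall oracle
  P <- matrix(0, 5, 5)
  P[1, 2] <- 0.5; P[2, 3] <- 0.25; P[3, 4] <- 1; P[4, 5] <- 0.2
  P <- P + t(P)
  expect_equal(global_efficiency(weighted_graph(P)),
               oracle_global_efficiency(P), tolerance = 1e-12)
})

test_that("local efficiency matches the naive per-node formula", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(local_efficiency(weighted_graph(tri)), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(local_efficiency(weighted_graph(star)), 0)
  W <- random_weighted_graph(8, 0.5, seed = 2)
  expect_equal(local_efficiency(weighted_graph(W)),
               oracle_local_efficiency(W), tolerance = 1e-12)
})

test_that("efficiencies match igraph where definitions coincide", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    W <- random_weighted_graph(10, 0.4, seed = s)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(global_efficiency(weighted_graph(W)),
                 igraph::global_efficiency(g, weights = 1 / igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency never decreases with sparsity", {
  set.seed(3)
  z <- matrix(rnorm(30 * 30, 0.1, 0.4), 30)
  z <- (z + t(z)) / 2; diag(z) <- 0
  effs <- vapply(seq(0.1, 0.5, by = 0.05), function(s) {
    global_efficiency(suppressMessages(proportional_threshold(z, s)))
  }, 0)
  expect_true(all(diff(effs) >= -1e-12))
})

test_that("rewired nulls preserve the weight multiset and degree sequence", {
  W <- random_weighted_graph(12, 0.4, seed = 4)
  g <- weighted_graph(W)
  nulls <- rewired_nulls(g, n_nulls = 10, seed = 3)
  for (nl in nulls) {
    expect_equal(sort(nl$weights[upper.tri(nl$weights) & nl$weights > 0]),
                 sort(W[upper.tri(W) & W > 0]))
    expect_equal(rowSums(nl$weights > 0), rowSums(W > 0), ignore_attr = TRUE)
  }
  # topology is actually destroyed for at least some nulls
  expect_true(any(vapply(nulls, function(nl) any((nl$weights > 0) != (W > 0)), TRUE)))
  # batch null metrics equal singly generated nulls (shared seed streams)
  ne <- cpp_null_efficiencies(W, 3L, 42, 10L)
  one <- cpp_rewired_null(W, 42, 0L, 10L)$weights
  expect_equal(ne[1, 1], global_efficiency(weighted_graph(one)), tolerance = 1e-12)
  # complete graph: no legal swap exists, weight shuffle on fixed topology
  K <- matrix(1, 5, 5) * matrix(runif(25, 0.5, 1), 5)
  K <- (K + t(K)) / 2; diag(K) <- 0
  expect_message(nk <- rewired_nulls(weighted_graph(K), 2, seed = 1),
                 "fell back")
  expect_equal(unname(nk[[1]]$weights > 0), K > 0)
})

test_that("null-normalized efficiency behaves on reference structures", {
  W <- random_weighted_graph(10, 0.5, seed = 5)
  g <- weighted_graph(W)
  # benchmarked against copies of itself: both ratios exactly 1
  self <- normalized_efficiency(g, list(g, g, g))
  expect_equal(self$global_norm, 1)
  expect_equal(self$local_norm, 1)
  # a ring lattice is locally clustered: normalized local efficiency > 1
  n <- 20
  L <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    L[i, j] <- L[j, i] <- 1 - 0.1 * d
  }
  lat <- weighted_graph(L)
  nl <- normalized_efficiency(lat, rewired_nulls(lat, 50, seed = 6))
  expect_gt(nl$local_norm, 1)
})

test_that("modularity optimization recovers planted structure", {
  # two disconnected unit-weight 4-cliques: Q = 2 x (1/2 - 1/4) = 1/2
  K <- matrix(0, 8, 8); K[1:4, 1:4] <- 1; K[5:8, 5:8] <- 1; diag(K) <- 0
  part <- modularity_partition(weighted_graph(K), n_runs = 10, seed = 1)
  expect_equal(part$q, 0.5, tolerance = 1e-12)
  expect_true(same_partition(part$assignment, rep(1:2, each = 4)))
  # complete graph has no structure: one module, Q = 0
  C <- matrix(1, 6, 6); diag(C) <- 0
  pc <- modularity_partition(weighted_graph(C), n_runs = 10, seed = 1)
  expect_equal(pc$q, 0, tolerance = 1e-12)
  expect_equal(pc$n_modules, 1L)
  # planted 3-module weighted graph recovered across seeds
  B <- matrix(0.1, 18, 18)
  for (m in 0:2) B[m * 6 + 1:6, m * 6 + 1:6] <- 0.6
  diag(B) <- 0
  hits <- vapply(1:20, function(s) {
    p <- modularity_partition(weighted_graph(B), n_runs = 20, seed = s)
    same_partition(p$assignment, rep(1:3, each = 6))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # Q of the returned partition at least matches the trivial single module
  W <- random_weighted_graph(15, 0.3, seed = 7)
  p <- modularity_partition(weighted_graph(W), n_runs = 10, seed = 2)
  expect_gte(p$q, modularity_q(weighted_graph(W), rep(1L, 15)))
  expect_equal(modularity_q(weighted_graph(W), rep(1L, 15)), 0, tolerance = 1e-12)
  expect_error(modularity_partition(weighted_graph(matrix(0, 3, 3))), "edge")
})

test_that("modularity Q agrees with independent implementations", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    W <- random_weighted_graph(12, 0.4, seed = s + 10)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(modularity_q(weighted_graph(W), memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
    expect_equal(modularity_q(weighted_graph(W), memb),
                 oracle_modularity_q(W, memb), tolerance = 1e-12)
    # and the optimizer reaches at least igraph's multilevel Q
    p <- modularity_partition(weighted_graph(W), n_runs = 20, seed = 1)
    set.seed(1)
    q_ig <- igraph::modularity(g, igraph::membership(igraph::cluster_louvain(g)),
                               weights = igraph::E(g)$weight)
    expect_gte(p$q + 1e-9, q_ig)
  }
})

test_that("mean rewired-null modularity falls below a planted graph's Q", {
  B <- matrix(0.1, 18, 18)
  for (m in 0:2) B[m * 6 + 1:6, m * 6 + 1:6] <- 0.6
  diag(B) <- 0
  g <- weighted_graph(B)
  q_obs <- modularity_partition(g, n_runs = 10, seed = 1)$q
  q_null <- vapply(rewired_nulls(g, 20, seed = 2), function(nl) {
    modularity_partition(nl, n_runs = 10, seed = 1)$q
  }, 0)
  expect_gt(q_obs, mean(q_null))
})

test_that("modular connectivity normalization and ratio are exact", {
  # equal weights: everything is 1
  K <- matrix(0, 6, 6); K[1:3, 1:3] <- 0.7; K[4:6, 4:6] <- 0.7
  K[1, 4] <- K[2, 5] <- 0.7
  K <- pmax(K, t(K)); diag(K) <- 0
  ii <- intra_inter_connectivity(weighted_graph(K), rep(1:2, each = 3))
  expect_equal(ii$intramodular_norm, 1)
  expect_equal(ii$intermodular_norm, 1)
  expect_equal(ii$ratio, 1)
  # within 0.8, between 0.4, equal counts: 4/3, 2/3, ratio 2
  M <- matrix(0, 4, 4)
  M[1, 2] <- 0.8; M[3, 4] <- 0.8   # within the two modules
  M[1, 3] <- 0.4; M[2, 4] <- 0.4   # between
  M <- M + t(M)
  ii2 <- intra_inter_connectivity(weighted_graph(M), c(1, 1, 2, 2))
  expect_equal(ii2$intramodular_norm, 0.8 / 0.6, tolerance = 1e-12)
  expect_equal(ii2$intermodular_norm, 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(ii2$ratio, 2, tolerance = 1e-12)
  # invariant under global rescaling
  ii3 <- intra_inter_connectivity(weighted_graph(3.7 * M), c(1, 1, 2, 2))
  expect_equal(unlist(ii3), unlist(ii2), tolerance = 1e-12)
  # per-module averaging variant stays scale-invariant too
  ii4 <- intra_inter_connectivity(weighted_graph(M), c(1, 1, 2, 2),
                                  per_module = TRUE)
  ii5 <- intra_inter_connectivity(weighted_graph(2 * M), c(1, 1, 2, 2),
                                  per_module = TRUE)
  expect_equal(unlist(ii4), unlist(ii5), tolerance = 1e-12)
  # no between-module edges is an error
  D <- matrix(0, 4, 4); D[1, 2] <- D[3, 4] <- 1; D <- D + t(D)
  expect_error(intra_inter_connectivity(weighted_graph(D), c(1, 1, 2, 2)),
               "between-module")
})

test_that("metric profiles integrate over the grid deterministically", {
  set.seed(8)
  cfg <- cohort_config(n_per_group = 1, n_rois = 18, module_sizes = c(6, 6, 6),
                       n_timepoints = 80, seed = 5)
  cm <- suppressMessages(panel_connectivity(
    simulate_subject(cfg, "groupB", 3)$panel))
  # single-level grid: integrated equals the level values
  pr1 <- suppressMessages(metric_profile(cm, sparsity_grid(0.4), n_nulls = 10,
                                         n_runs = 5, seed = 2))
  expect_equal(unname(pr1$integrated),
               unname(unlist(pr1$per_level[1, -1])), tolerance = 1e-12)
  # default grid has 9 levels and the mean-over-levels contract holds
  pr9 <- suppressMessages(metric_profile(cm, n_nulls = 5, n_runs = 5, seed = 2))
  expect_equal(nrow(pr9$per_level), 9)
  expect_equal(unname(pr9$integrated["modularity_q"]),
               mean(pr9$per_level$modularity_q, na.rm = TRUE))
  # ratio column is consistent at every defined level
  ok <- !is.na(pr9$per_level$intra_inter_ratio)
  expect_equal(pr9$per_level$intra_inter_ratio[ok],
               pr9$per_level$intramodular_norm[ok] /
                 pr9$per_level$intermodular_norm[ok], tolerance = 1e-10)
  # identical inputs and seeds give identical profiles
  pr9b <- suppressMessages(metric_profile(cm, n_nulls = 5, n_runs = 5, seed = 2))
  expect_identical(pr9$per_level, pr9b$per_level)
})
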