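# Independent pure-R oracles used to cross-check the compiled implementations.
# Deliberately naive: direct transcriptions of the defining formulas.

oracle_fw_distances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  d <- oracle_fw_distances(W)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  total <- 0
  for (u in seq_len(n)) {
    nb <- which(W[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- W[nb, nb, drop = FALSE]^(1 / 3)
    dn <- nrow(sub)
    d <- matrix(Inf, dn, dn)
    diag(d) <- 0
    d[sub > 0] <- 1 / sub[sub > 0]
    for (kk in seq_len(dn))
      for (i in seq_len(dn))
        for (j in seq_len(dn))
          if (d[i, kk] + d[kk, j] < d[i, j]) d[i, j] <- d[i, kk] + d[kk, j]
    num <- 0
    for (a in seq_len(k))
      for (b in seq_len(k))
        if (a != b && is.finite(d[a, b]))
          num <- num + (W[u, nb[a]] * W[u, nb[b]])^(1 / 3) / d[a, b]
    total <- total + num / (k * (k - 1))
  }
  total / n
}

oracle_modularity_q <- function(W, comm) {
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (c in unique(comm)) {
    inC <- comm == c
    q <- q + sum(W[inC, inC]) / m2 - (sum(k[inC]) / m2)^2
  }
  q
}

random_weighted_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[runif(length(up)) < p_edge]
  W[on] <- runif(length(on), 0.05, 1)
  W + t(W)
}

# TRUE when two hard partitions are identical up to module relabelling
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# feature-space cohorts (subjects x features), group B shifted on the first
# n_signal features by `effect` standard deviations
make_signal_features <- function(n_per_group = 40, p = 990, n_signal = 0,
                                 effect = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p)
  if (n_signal > 0)
    X[(n_per_group + 1):(2 * n_per_group), seq_len(n_signal)] <-
      X[(n_per_group + 1):(2 * n_per_group), seq_len(n_signal)] + effect
  labeled_feature_set(X, rep(c("groupA", "groupB"), each = n_per_group))
}

# full-pipeline cohort with no group contrast (both groups share the same
# modular structure), labels shuffled so they are independent of the data
make_null_cohort_features <- function(seed, n_per_group = 40) {
  cfg <- cohort_config(n_per_group = n_per_group,
                       intra_r = c(0.5, 0.5), inter_r = c(0.2, 0.2),
                       seed = seed)
  ch <- simulate_cohort(cfg)
  mats <- suppressMessages(lapply(ch$subjects,
                                  function(s) panel_connectivity(s$panel)))
  tab <- ch$table
  set.seed(seed + 7)
  tab$group <- sample(tab$group)
  feature_set_from_matrices(mats, tab)
}
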