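#' Weighted undirected graph
#'
#' Nonnegative, symmetric, zero-diagonal weight matrix: the thresholded
#' network at one sparsity level.
#'
#' @param weights symmetric numeric matrix with zero diagonal and
#'   nonnegative entries.
#' @param node_names optional node labels.
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights, node_names = NULL) {
  weights <- as.matrix(weights)
  check_symmetric(weights, what = "weight matrix")
  stop_if_not(all(diag(weights) == 0), "diagonal must be zero")
  stop_if_not(all(weights >= 0), "weights must be nonnegative")
  node_names <- node_names %||% colnames(weights) %||%
    default_roi_names(ncol(weights))
  dimnames(weights) <- list(node_names, node_names)
  structure(list(weights = weights, node_names = node_names),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- ncol(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_graph> %d nodes, %d edges (sparsity %.3f)\n",
              n, m, m / (n * (n - 1) / 2)))
  invisible(x)
}

graph_weights <- function(g) {
  if (inherits(g, "weighted_graph")) g$weights
  else if (inherits(g, "conn_matrix")) g$z
  else as.matrix(g)
}

#' Sparsity grid
#'
#' The ordered set of proportional-threshold levels over which the topology
#' metrics are integrated; the default 10% to 50% in steps of 5% keeps the
#' graphs densely connected while still separating them from random topology.
#'
#' @param levels strictly increasing fractions in `(0, 1]`.
#' @return An object of class `sparsity_grid`.
#' @export
sparsity_grid <- function(levels = seq(0.10, 0.50, by = 0.05)) {
  stop_if_not(length(levels) >= 1 && all(levels > 0) && all(levels <= 1),
              "levels must be in (0, 1]")
  stop_if_not(all(diff(levels) > 0), "levels must be strictly increasing")
  structure(list(levels = levels), class = "sparsity_grid")
}

#' Proportional sparsity threshold
#'
#' Zeroes all negative entries (the traditional treatment of negative
#' resting-state correlations), then keeps the `round(sparsity * n(n-1)/2)`
#' largest positive upper-triangle weights — equating edge count, i.e. wiring
#' cost, across subjects — and zeroes the rest. Retained weights keep their
#' values. Rounding is half-away-from-zero; ties among equal weights at the
#' cut are resolved by (row, column) lexicographic order. If fewer positive
#' entries exist than requested, all positives are kept and the achieved
#' sparsity is logged.
#'
#' @param matrix a `conn_matrix`, `weighted_graph`, or symmetric matrix.
#' @param sparsity fraction of possible edges to retain, in `(0, 1]`.
#' @return A [weighted_graph()].
#' @export
proportional_threshold <- function(matrix, sparsity) {
  stop_if_not(is_number(sparsity) && sparsity > 0 && sparsity <= 1,
              "sparsity must be in (0, 1]")
  w <- graph_weights(matrix)
  check_symmetric(w, what = "connectivity matrix")
  diag(w) <- 0
  w[w < 0] <- 0
  n <- ncol(w)
  pairs <- upper_pairs(n)
  vals <- w[pairs]
  m_target <- round_half_up(sparsity * n * (n - 1) / 2)
  pos <- which(vals > 0)
  if (length(pos) < m_target) {
    ht_log(sprintf("only %d positive entries for %d requested edges; achieved sparsity %.3f",
                   length(pos), m_target, length(pos) / (n * (n - 1) / 2)))
    keep <- pos
  } else {
    ord <- order(-vals, pairs[, "i"], pairs[, "j"])
    keep <- ord[seq_len(m_target)]
  }
  out <- matrix(0, n, n)
  kp <- pairs[keep, , drop = FALSE]
  out[kp] <- vals[keep]
  out <- out + t(out)
  colnames(out) <- rownames(out) <- colnames(w) %||% default_roi_names(n)
  weighted_graph(out)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' edge lengths `1/weight`; unreachable pairs contribute 0, so the measure is
#' defined on disconnected graphs (its advantage over the characteristic
#' path length). An integration proxy.
#'
#' @param graph a [weighted_graph()].
#' @return Nonnegative scalar.
#' @export
global_efficiency <- function(graph) {
  cpp_global_efficiency(graph_weights(graph))
}

#' Weighted local efficiency
#'
#' Per node, the efficiency of communication among its first neighbours with
#' the node removed: shortest paths on the neighbour subgraph with
#' cube-root-symmetrized weight scaling by the edges connecting each
#' neighbour pair to the centre node. Nodes with fewer than two neighbours
#' contribute 0; the nodal mean is returned. A segregation proxy.
#'
#' @param graph a [weighted_graph()].
#' @return Nonnegative scalar.
#' @export
local_efficiency <- function(graph) {
  cpp_local_efficiency(graph_weights(graph))
}

#' Degree-preserving rewired null networks
#'
#' Each null is built by seeded double-edge swaps (about `swaps_per_edge`
#' attempts per edge) that preserve the degree sequence and destroy the
#' low-level topology, followed by random reassignment of the original
#' weight multiset to the rewired edges — so both the degree sequence and
#' the exact weight distribution of the input are preserved. On graphs too
#' dense or too sparse for any successful swap the null degenerates to a
#' weight shuffle on the original topology, which is logged.
#'
#' @param graph a [weighted_graph()] with at least 4 edges.
#' @param n_nulls number of null networks (default 1000).
#' @param seed base seed; null `i` is reproducible in isolation.
#' @param swaps_per_edge swap attempts per edge (default 10).
#' @return List of `weighted_graph` objects.
#' @export
rewired_nulls <- function(graph, n_nulls = 1000, seed = 1, swaps_per_edge = 10) {
  w <- graph_weights(graph)
  m <- sum(w[upper.tri(w)] > 0)
  stop_if_not(m >= 4, "need at least 4 edges to rewire")
  out <- vector("list", n_nulls)
  n_fallback <- 0L
  for (i in seq_len(n_nulls)) {
    nl <- cpp_rewired_null(w, seed, i - 1L, as.integer(swaps_per_edge))
    if (nl$n_swaps == 0L) n_fallback <- n_fallback + 1L
    out[[i]] <- weighted_graph(nl$weights, colnames(w))
  }
  if (n_fallback > 0)
    ht_log(n_fallback, " null(s) fell back to a weight shuffle on the original topology")
  out
}

#' Null-normalized efficiency
#'
#' Observed global and local efficiency divided by their means over the null
#' networks; values above 1 indicate more efficient (or more clustered)
#' organization than degree- and weight-matched chance.
#'
#' @param graph a [weighted_graph()].
#' @param nulls list of null graphs from [rewired_nulls()].
#' @return List with `global_norm` and `local_norm`.
#' @export
normalized_efficiency <- function(graph, nulls) {
  stop_if_not(length(nulls) >= 1, "nulls must be non-empty")
  ge <- global_efficiency(graph)
  le <- local_efficiency(graph)
  ng <- mean(vapply(nulls, global_efficiency, 0))
  nl <- mean(vapply(nulls, local_efficiency, 0))
  stop_if_not(ng > 0 && nl > 0, "null mean efficiency is zero")
  list(global_norm = ge / ng, local_norm = le / nl)
}

#' Weighted modularity partition
#'
#' Partitions the network into nonoverlapping modules by multi-level greedy
#' modularity optimization with `n_runs` seeded restarts (random node orders);
#' the partition with the best weighted Newman modularity Q wins, ties going
#' to the first found. Deterministic given the seed.
#'
#' @param graph a [weighted_graph()] with at least one edge.
#' @param n_runs number of restarts (default 100).
#' @param seed seed for the restart streams.
#' @return An object of class `module_partition`: `assignment` (named module
#'   id per node), `q`, `n_modules`, `n_runs`, `seed`.
#' @export
modularity_partition <- function(graph, n_runs = 100, seed = 1) {
  w <- graph_weights(graph)
  stop_if_not(sum(w[upper.tri(w)] > 0) >= 1, "graph has no edges")
  lv <- cpp_louvain(w, as.integer(n_runs), seed)
  assignment <- stats::setNames(as.integer(lv$membership),
                                colnames(w) %||% default_roi_names(ncol(w)))
  structure(list(assignment = assignment, q = lv$q,
                 n_modules = lv$n_modules, n_runs = n_runs, seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.4f (%d restarts)\n",
              x$n_modules, x$q, x$n_runs))
  invisible(x)
}

#' Modularity Q of a given partition
#'
#' @param graph a [weighted_graph()].
#' @param assignment integer module id per node.
#' @return Weighted Newman modularity in `[-1, 1]`.
#' @export
modularity_q <- function(graph, assignment) {
  cpp_modularity_q(graph_weights(graph), as.integer(assignment))
}

#' Intra- and intermodular connectivity
#'
#' Mean edge weight within modules and between modules, each normalized by
#' the mean weight over all retained edges — removing global differences in
#' correlation magnitude across individuals — plus their ratio
#' (segregation/integration balance). The default pools edges across
#' modules; `per_module = TRUE` instead averages the per-module means before
#' normalizing.
#'
#' @param graph a [weighted_graph()].
#' @param partition a [modularity_partition()] result (or an integer
#'   assignment vector covering every node).
#' @return List with `intramodular_norm`, `intermodular_norm`, `ratio`.
#' @param per_module average within-module means per module instead of
#'   pooling edges.
#' @export
intra_inter_connectivity <- function(graph, partition, per_module = FALSE) {
  w <- graph_weights(graph)
  assignment <- if (inherits(partition, "module_partition")) partition$assignment
                else as.integer(partition)
  stop_if_not(length(assignment) == ncol(w),
              "partition must cover every node")
  pairs <- upper_pairs(ncol(w))
  vals <- w[pairs]
  retained <- vals > 0
  same <- assignment[pairs[, "i"]] == assignment[pairs[, "j"]]
  stop_if_not(any(retained & !same),
              "no between-module edges: intermodular connectivity undefined for this partition")
  mean_all <- mean(vals[retained])
  if (per_module) {
    mods <- sort(unique(assignment))
    per <- vapply(mods, function(m) {
      e <- retained & same & assignment[pairs[, "i"]] == m
      if (any(e)) mean(vals[e]) else NA_real_
    }, 0)
    intra <- mean(per, na.rm = TRUE) / mean_all
  } else {
    stop_if_not(any(retained & same), "no within-module edges")
    intra <- mean(vals[retained & same]) / mean_all
  }
  inter <- mean(vals[retained & !same]) / mean_all
  list(intramodular_norm = intra, intermodular_norm = inter,
       ratio = intra / inter)
}

#' Topology metric profile over the sparsity range
#'
#' Computes the six network metrics — null-normalized global and local
#' efficiency, modularity Q, normalized intra- and intermodular connectivity
#' and their ratio — at every sparsity level of the grid, and integrates each
#' as the unweighted mean across the levels at which it is defined
#' (normalized area under the curve on an even grid). At low sparsity a
#' strongly modular network can retain no between-module edge at all; the
#' modular-connectivity triple is then undefined at that level, recorded as
#' missing, and the subject flagged. The modularity partition is
#' re-estimated at every level.
#' Fully reproducible given the seed; per-level failures are recorded and
#' flag the subject.
#'
#' @param matrix a `conn_matrix` (or symmetric matrix).
#' @param grid a [sparsity_grid()].
#' @param n_nulls rewired nulls per level (default 1000).
#' @param n_runs modularity restarts per level (default 100).
#' @param seed seed; per-level streams are derived from it.
#' @param swaps_per_edge rewiring intensity.
#' @param subject_id id carried into the output.
#' @return An object of class `metric_profile`: `per_level` (data.frame with
#'   one row per sparsity level), `integrated` (named numeric of the six
#'   metrics), `partitions` (list of per-level assignments), `failed` flag.
#' @export
metric_profile <- function(matrix, grid = sparsity_grid(), n_nulls = 1000,
                           n_runs = 100, seed = 1, swaps_per_edge = 10,
                           subject_id = NULL) {
  if (inherits(matrix, "conn_matrix")) {
    subject_id <- subject_id %||% matrix$subject_id
  }
  subject_id <- subject_id %||% "subject"
  levels <- grid$levels
  metrics <- c("global_efficiency_norm", "local_efficiency_norm",
               "modularity_q", "intramodular_norm", "intermodular_norm",
               "intra_inter_ratio")
  per_level <- data.frame(sparsity = levels)
  for (m in metrics) per_level[[m]] <- NA_real_
  partitions <- vector("list", length(levels))
  failed <- FALSE
  record_failure <- function(li, e) {
    failed <<- TRUE
    ht_log(sprintf("subject %s, sparsity %.2f failed: %s", subject_id,
                   levels[li], conditionMessage(e)))
  }
  for (li in seq_along(levels)) {
    tryCatch({
      g <- proportional_threshold(matrix, levels[li])
      w <- g$weights
      ge <- cpp_global_efficiency(w)
      le <- cpp_local_efficiency(w)
      ne <- cpp_null_efficiencies(w, as.integer(n_nulls),
                                  derive_stream_seed(seed, li * 2L),
                                  as.integer(swaps_per_edge))
      null_ge <- mean(ne[, 1]); null_le <- mean(ne[, 2])
      stop_if_not(null_ge > 0 && null_le > 0, "null mean efficiency is zero")
      part <- modularity_partition(g, n_runs = n_runs,
                                   seed = derive_stream_seed(seed, li * 2L + 1L))
      per_level[li, metrics[1:3]] <- c(ge / null_ge, le / null_le, part$q)
      partitions[[li]] <- part$assignment
      # the modular-connectivity triple can be undefined on its own (a
      # partition with no between-module edges) without voiding the rest
      tryCatch({
        ii <- intra_inter_connectivity(g, part)
        per_level[li, metrics[4:6]] <- c(ii$intramodular_norm,
                                         ii$intermodular_norm, ii$ratio)
      }, error = function(e) record_failure(li, e))
    }, error = function(e) record_failure(li, e))
  }
  integrated <- colMeans(per_level[, metrics, drop = FALSE], na.rm = TRUE)
  integrated[is.nan(integrated)] <- NA_real_
  structure(list(subject_id = subject_id, per_level = per_level,
                 integrated = integrated, partitions = partitions,
                 failed = failed, grid = levels,
                 n_nulls = n_nulls, n_runs = n_runs, seed = seed),
            class = "metric_profile")
}

#' @export
print.metric_profile <- function(x, ...) {
  cat(sprintf("<metric_profile> %s over %d sparsity level(s)%s\n", x$subject_id,
              length(x$grid), if (x$failed) " [FLAGGED: per-level failure]" else ""))
  print(round(x$integrated, 4))
  invisible(x)
}

#' Metric profiles for a whole cohort
#'
#' @param matrices list of `conn_matrix` objects.
#' @param grid,n_nulls,n_runs,swaps_per_edge as in [metric_profile()].
#' @param seed base seed; each subject derives its own stream from it.
#' @param partitions_dir if non-`NULL`, per-subject module assignments are
#'   written there as CSV (columns: sparsity, node, module).
#' @return A data.frame with one row per subject: `subject_id`, the six
#'   integrated metrics, and per-level columns `<metric>_s<level>`.
#' @export
cohort_profiles <- function(matrices, grid = sparsity_grid(), n_nulls = 1000,
                            n_runs = 100, seed = 1, swaps_per_edge = 10,
                            partitions_dir = NULL) {
  if (!is.null(partitions_dir))
    dir.create(partitions_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(matrices), function(i) {
    pr <- metric_profile(matrices[[i]], grid = grid, n_nulls = n_nulls,
                         n_runs = n_runs,
                         seed = derive_stream_seed(seed, i),
                         swaps_per_edge = swaps_per_edge)
    if (!is.null(partitions_dir)) write_partition_csv(pr, partitions_dir)
    row <- data.frame(subject_id = pr$subject_id, t(pr$integrated),
                      failed = pr$failed, stringsAsFactors = FALSE)
    for (m in names(pr$integrated)) {
      lv <- pr$per_level[[m]]
      names(lv) <- sprintf("%s_s%02.0f", m, 100 * pr$per_level$sparsity)
      row <- cbind(row, as.data.frame(as.list(lv)))
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a subject's per-level module assignments as CSV
#'
#' One row per (sparsity level, node) with the module id assigned at that
#' level; levels where the partition failed are omitted.
#'
#' @param profile a [metric_profile()].
#' @param dir output directory.
#' @return The file path, invisibly.
#' @export
write_partition_csv <- function(profile, dir) {
  rows <- list()
  for (li in seq_along(profile$grid)) {
    a <- profile$partitions[[li]]
    if (is.null(a)) next
    rows[[li]] <- data.frame(sparsity = profile$grid[li], node = names(a),
                             module = as.integer(a), stringsAsFactors = FALSE)
  }
  path <- file.path(dir, paste0(profile$subject_id, "_partitions.csv"))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write cohort metric profiles as CSV
#'
#' @param profiles data.frame from [cohort_profiles()].
#' @param path output path.
#' @export
write_metric_csv <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
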