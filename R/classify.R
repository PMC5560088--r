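#' Labeled feature set
#'
#' Subjects-by-features matrix with binary group labels, the backbone of the
#' multivariate pattern classification arm. The first label level plays the
#' specificity role (slow-growing group), the second the sensitivity role.
#'
#' @param features numeric matrix, subjects x features, finite.
#' @param labels vector with exactly two distinct values; coerced to factor.
#' @param subject_ids optional ids.
#' @param index_map optional feature-to-ROI-pair map from
#'   [vectorize_upper_triangle()].
#' @return An object of class `feature_set`.
#' @export
labeled_feature_set <- function(features, labels, subject_ids = NULL,
                                index_map = NULL) {
  features <- as.matrix(features)
  stop_if_not(all(is.finite(features)), "features must be finite")
  labels <- as.factor(labels)
  stop_if_not(nlevels(labels) == 2 && all(table(labels) > 0),
              "exactly two label values must be present")
  stop_if_not(length(labels) == nrow(features),
              "one label per subject required")
  structure(list(features = features, labels = labels,
                 subject_ids = subject_ids %||% rownames(features) %||%
                   sprintf("S%03d", seq_len(nrow(features))),
                 index_map = index_map),
            class = "feature_set")
}

#' Assemble a feature set from connectivity matrices
#'
#' @param matrices list of `conn_matrix` objects (one per subject).
#' @param table cohort table with `subject_id` and `group` columns; rows are
#'   matched to `matrices` by position.
#' @return A `feature_set`.
#' @export
feature_set_from_matrices <- function(matrices, table) {
  stop_if_not(length(matrices) == nrow(table),
              "one matrix per cohort row required")
  fvs <- lapply(matrices, vectorize_upper_triangle)
  features <- do.call(rbind, lapply(fvs, `[[`, "values"))
  rownames(features) <- table$subject_id
  labeled_feature_set(features, table$group, subject_ids = table$subject_id,
                      index_map = fvs[[1]]$index_map)
}

labels01 <- function(labels) as.integer(labels) - 1L

#' Kendall tau-b discriminative power
#'
#' Absolute tau-b rank correlation between one feature and the binary labels,
#' the tie-corrected variant (labels are massively tied by construction).
#' Computed by exact pair enumeration; a constant feature has power 0.
#'
#' @param feature_column per-subject feature values.
#' @param labels binary labels.
#' @return Nonnegative power in `[0, 1]`.
#' @export
kendall_power <- function(feature_column, labels) {
  labels <- as.factor(labels)
  stop_if_not(length(feature_column) >= 2 && nlevels(droplevels(labels)) == 2,
              "need >= 2 subjects with both labels present")
  as.numeric(cpp_kendall_powers(matrix(as.numeric(feature_column), ncol = 1),
                                labels01(labels)))
}

#' Rank features by discriminative power
#'
#' Indices of the `k` features with the largest absolute tau-b against the
#' labels, in decreasing order of power; ties are broken by ascending feature
#' index so the ordering is deterministic.
#'
#' @param train a `feature_set` (the training portion of a fold).
#' @param k number of features to keep.
#' @return Integer vector of `k` feature indices.
#' @export
rank_features <- function(train, k) {
  stop_if_not(inherits(train, "feature_set"), "train must be a feature_set")
  p <- ncol(train$features)
  stop_if_not(is_count(k) && k <= p, "k must be a count <= number of features")
  powers <- as.numeric(cpp_kendall_powers(train$features, labels01(train$labels)))
  order(-powers, seq_len(p))[seq_len(k)]
}

#' Consensus feature selection across leave-one-out folds
#'
#' For each leave-one-out fold the features are ranked on the n-1 training
#' subjects only; the consensus set contains the features present in every
#' fold's top-k. Because folds share all but one subject the rankings are
#' strongly correlated and the consensus is typically a large fraction of k.
#'
#' @param dataset a `feature_set`.
#' @param k top-k size per fold (default 200).
#' @return An object of class `consensus_selection`: `per_fold_rankings`
#'   (k x n matrix of feature indices, one column per held-out subject), `k`,
#'   and `consensus` (sorted feature indices).
#' @export
consensus_features <- function(dataset, k = 200) {
  stop_if_not(inherits(dataset, "feature_set"), "dataset must be a feature_set")
  n <- nrow(dataset$features)
  stop_if_not(n >= 3, "need at least 3 subjects")
  stop_if_not(is_count(k) && k <= ncol(dataset$features),
              "k must be a count <= number of features")
  folds <- cpp_fold_topk(dataset$features, labels01(dataset$labels), as.integer(k))
  colnames(folds) <- dataset$subject_ids
  cons <- sort(Reduce(intersect, lapply(seq_len(n), function(m) folds[, m])))
  if (!length(cons)) warning("empty consensus feature set", call. = FALSE)
  structure(list(per_fold_rankings = folds, k = k, consensus = cons),
            class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("<consensus_selection> top-%d per fold, %d fold(s), %d consensus feature(s)\n",
              x$k, ncol(x$per_fold_rankings), length(x$consensus)))
  invisible(x)
}

classification_result <- function(pred, labels, subject_ids, n_perm = 0L,
                                  permutation_p = NULL, null_accuracy = NULL,
                                  consensus = NULL) {
  lv <- levels(labels)
  spec <- mean(pred[labels == lv[1]] == lv[1])
  sens <- mean(pred[labels == lv[2]] == lv[2])
  structure(list(per_subject_prediction = stats::setNames(pred, subject_ids),
                 specificity = spec, sensitivity = sens,
                 overall_accuracy = (spec + sens) / 2,
                 permutation_p = permutation_p, n_permutations = n_perm,
                 null_accuracy = null_accuracy, consensus = consensus),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> overall %.3f (specificity %.3f, sensitivity %.3f)\n",
              x$overall_accuracy, x$specificity, x$sensitivity))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Leave-one-out linear SVM classification
#'
#' For each subject in turn a linear soft-margin SVM (cost `cost`) is trained
#' on the remaining subjects restricted to the consensus features, and the
#' held-out subject is predicted. Specificity is the accuracy on the first
#' label level, sensitivity on the second, and the overall accuracy is their
#' mean.
#'
#' @param dataset a `feature_set`.
#' @param selection a `consensus_selection` (non-empty), or an integer vector
#'   of feature indices.
#' @param cost SVM regularization constant (default 1).
#' @return A `classification_result`.
#' @export
loocv_classify <- function(dataset, selection, cost = 1) {
  stop_if_not(inherits(dataset, "feature_set"), "dataset must be a feature_set")
  idx <- if (inherits(selection, "consensus_selection")) selection$consensus
         else as.integer(selection)
  stop_if_not(length(idx) >= 1, "consensus feature set is empty")
  y <- labels01(dataset$labels)
  pred01 <- cpp_svm_loocv(dataset$features[, idx, drop = FALSE], y, cost)
  pred <- levels(dataset$labels)[pred01 + 1L]
  classification_result(pred, dataset$labels, dataset$subject_ids,
                        consensus = idx)
}

#' Nested (honest) leave-one-out classification
#'
#' Unbiased accuracy estimate: each fold's SVM is restricted to that fold's
#' own training-only top-k ranking, with no consensus intersection across
#' folds. Unlike the fixed-consensus estimate of [loocv_classify()] — whose
#' value is interpretable only against its permutation null, because the
#' consensus set conditions on rank correlations that involve every held-out
#' subject — this estimator sits at chance when labels carry no information.
#'
#' @param dataset a `feature_set`.
#' @param k top-k features per fold (default 200).
#' @param cost SVM regularization constant.
#' @return A `classification_result`.
#' @export
nested_loocv_classify <- function(dataset, k = 200, cost = 1) {
  stop_if_not(inherits(dataset, "feature_set"), "dataset must be a feature_set")
  y <- labels01(dataset$labels)
  res <- cpp_honest_loocv(dataset$features, y, as.integer(k), cost)
  pred <- levels(dataset$labels)[res$predictions + 1L]
  classification_result(pred, dataset$labels, dataset$subject_ids)
}

#' Stratified k-fold linear SVM classification
#'
#' Alternative splitter to leave-one-out: group-stratified folds, feature
#' ranking recomputed inside each training split, consensus across folds,
#' then per-fold SVM prediction.
#'
#' @param dataset a `feature_set`.
#' @param k top-k features per fold.
#' @param n_folds number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param cost SVM regularization constant.
#' @return A `classification_result` (with the consensus used).
#' @export
kfold_classify <- function(dataset, k = 200, n_folds = 10, seed = 1, cost = 1) {
  stop_if_not(inherits(dataset, "feature_set"), "dataset must be a feature_set")
  n <- nrow(dataset$features)
  stop_if_not(is_count(n_folds) && n_folds >= 2 && n_folds <= n,
              "n_folds must be between 2 and n")
  y <- labels01(dataset$labels)
  set.seed(seed)
  fold <- integer(n)
  for (g in 0:1) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  topk <- lapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    powers <- as.numeric(cpp_kendall_powers(
      dataset$features[tr, , drop = FALSE], y[tr]))
    order(-powers, seq_len(ncol(dataset$features)))[seq_len(k)]
  })
  cons <- sort(Reduce(intersect, topk))
  stop_if_not(length(cons) >= 1, "consensus feature set is empty")
  pred01 <- integer(n)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- cpp_svm_train(dataset$features[tr, cons, drop = FALSE], y[tr], cost)
    dec <- dataset$features[!tr, cons, drop = FALSE] %*% fit$w + fit$b
    pred01[!tr] <- as.integer(dec > 0)
  }
  pred <- levels(dataset$labels)[pred01 + 1L]
  classification_result(pred, dataset$labels, dataset$subject_ids,
                        consensus = cons)
}

#' Permutation test of the classification accuracy
#'
#' The observed accuracy comes from the unpermuted pipeline (consensus
#' selection within leave-one-out folds, then LOOCV SVM on the consensus).
#' For each permutation the labels are shuffled once and, in the default
#' nested mode, the entire pipeline — including per-fold feature ranking —
#' is rerun, so selection never sees the true labels. `nested = FALSE`
#' instead keeps the observed consensus features fixed and only refits the
#' classifiers. The p value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)` with `>=` counting, so it is
#' never zero.
#'
#' @param dataset a `feature_set`.
#' @param k top-k features per fold (default 200).
#' @param n_perm number of label permutations (default 10000).
#' @param seed seed for the permutation stream.
#' @param cost SVM regularization constant.
#' @param nested rerun feature selection per permutation (default TRUE).
#' @return A `classification_result` with `permutation_p` and the null
#'   accuracy distribution.
#' @export
permutation_test_accuracy <- function(dataset, k = 200, n_perm = 10000,
                                      seed = 1, cost = 1, nested = TRUE) {
  stop_if_not(inherits(dataset, "feature_set"), "dataset must be a feature_set")
  stop_if_not(is_count(n_perm), "n_perm must be a positive integer")
  y <- labels01(dataset$labels)
  obs <- cpp_nested_classify(dataset$features, y, as.integer(k), cost)
  stop_if_not(!obs$empty_consensus,
              "observed consensus feature set is empty; nothing to test")
  null <- cpp_permutation_null(dataset$features, y, as.integer(k), cost,
                               as.integer(n_perm), seed, nested,
                               as.integer(obs$consensus))
  if (null$n_empty_consensus > 0) {
    ht_log(null$n_empty_consensus,
           " permutation(s) had an empty consensus; chance accuracy recorded")
  }
  p <- (1 + sum(null$null_accuracy >= obs$overall_accuracy)) / (1 + n_perm)
  pred <- levels(dataset$labels)[obs$predictions + 1L]
  classification_result(pred, dataset$labels, dataset$subject_ids,
                        n_perm = as.integer(n_perm), permutation_p = p,
                        null_accuracy = as.numeric(null$null_accuracy),
                        consensus = as.integer(obs$consensus))
}

#' Write a classification report as JSON
#'
#' Per-subject predictions, specificity/sensitivity/overall accuracy, the
#' consensus features (with ROI-pair names when an index map is available),
#' the permutation p and a histogram of the null accuracies.
#'
#' @param result a `classification_result`.
#' @param path output path.
#' @param index_map optional feature index map.
#' @return The path, invisibly.
#' @export
write_classification_json <- function(result, path, index_map = NULL) {
  cons <- result$consensus
  cons_names <- if (!is.null(index_map) && length(cons)) {
    paste(index_map$roi_i[cons], index_map$roi_j[cons], sep = "--")
  } else NULL
  hist_counts <- NULL
  if (!is.null(result$null_accuracy)) {
    br <- seq(0, 1, by = 0.05)
    h <- hist(result$null_accuracy, breaks = br, plot = FALSE)
    hist_counts <- list(breaks = br, counts = h$counts)
  }
  out <- list(per_subject_prediction = as.list(result$per_subject_prediction),
              specificity = result$specificity,
              sensitivity = result$sensitivity,
              overall_accuracy = result$overall_accuracy,
              permutation_p = result$permutation_p,
              n_permutations = result$n_permutations,
              consensus_features = cons, consensus_roi_pairs = cons_names,
              null_accuracy_histogram = hist_counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
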