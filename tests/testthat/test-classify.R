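test_that("kendall power is tie-corrected tau-b", {
  # perfect concordance: with binary labels the label ties cap |tau-b| at
  # sqrt(n_a n_b / N); for 2 vs 2 that is 4 / sqrt(6 * 4)
  expect_equal(kendall_power(c(1, 2, 10, 11), c("a", "a", "b", "b")),
               4 / sqrt(24), tolerance = 1e-12)
  # ... and perfect separation still ranks above everything imperfect
  expect_gt(kendall_power(c(1, 2, 10, 11), c("a", "a", "b", "b")),
            kendall_power(c(1, 10, 2, 11), c("a", "a", "b", "b")))
  # brute-force pair enumeration: C = 3, D = 1, Ty = 2 label ties, no x ties
  # tau_b = (3 - 1) / sqrt(6 * (6 - 2)) = 2 / sqrt(24)
  expect_equal(kendall_power(c(1, 2, 3, 4), c(0, 1, 0, 1)), 2 / sqrt(24),
               tolerance = 1e-12)
  # constant feature: all pairs tied
  expect_equal(kendall_power(rep(3, 6), rep(c(0, 1), 3)), 0)
  # agreement with the base-R implementation across random data incl. x ties
  set.seed(1)
  for (rep in 1:20) {
    x <- sample(1:6, 30, replace = TRUE) + rnorm(30, sd = ifelse(rep %% 2, 0, 1))
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(kendall_power(x, y), abs(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
  # null mean of |tau-b| under label shuffles matches a direct Monte Carlo
  set.seed(2)
  x <- rnorm(40)
  y <- rep(0:1, 20)
  powers <- replicate(500, kendall_power(x, sample(y)))
  oracle <- replicate(500, abs(cor(x, sample(y), method = "kendall")))
  expect_lt(abs(mean(powers) - mean(oracle)), 0.02)
})

test_that("feature ranking is deterministic with index tie-break", {
  set.seed(3)
  n <- 30
  X <- matrix(rnorm(n * 50), n)
  y <- rep(c("a", "b"), each = n / 2)
  X[, 7] <- ifelse(y == "b", 10, 0) + rnorm(n, sd = 0.01) # separating feature
  fs <- labeled_feature_set(X, y)
  expect_equal(rank_features(fs, 1), 7L)
  # k = p returns all features sorted by power, descending
  all_idx <- rank_features(fs, 50)
  powers <- vapply(seq_len(50), function(j) kendall_power(X[, j], y), 0)
  expect_equal(all_idx, order(-powers, seq_len(50)))
  # exact duplicates tie and the lower index wins
  X2 <- cbind(X[, 7], X[, 7], X[, 7])
  fs2 <- labeled_feature_set(X2, y)
  expect_equal(rank_features(fs2, 2), c(1L, 2L))
})

test_that("consensus selection intersects per-fold top-k sets", {
  fs <- make_signal_features(n_per_group = 10, p = 60, n_signal = 10,
                             effect = 4, seed = 4)
  sel <- consensus_features(fs, k = 10)
  expect_setequal(sel$consensus, 1:10)
  expect_true(all(sel$consensus %in% sel$per_fold_rankings[, 3]))
  # k = p: consensus is everything
  expect_length(consensus_features(fs, k = 60)$consensus, 60)
  # per-fold rankings match a direct leave-one-out recomputation
  m <- 5
  sub <- labeled_feature_set(fs$features[-m, ], fs$labels[-m])
  expect_equal(sort(sel$per_fold_rankings[, m]), sort(rank_features(sub, 10)))
})

test_that("a fold's ranking never sees its held-out subject", {
  fs <- make_signal_features(n_per_group = 8, p = 40, n_signal = 5,
                             effect = 1, seed = 5)
  sel <- consensus_features(fs, k = 10)
  spiked <- fs$features
  spiked[3, ] <- spiked[3, ] + 1e6  # extreme held-out values
  sel2 <- consensus_features(labeled_feature_set(spiked, fs$labels), k = 10)
  expect_equal(sel$per_fold_rankings[, 3], sel2$per_fold_rankings[, 3])
})

test_that("LOOCV accuracy arithmetic and symmetry hold", {
  fs <- make_signal_features(n_per_group = 10, p = 30, n_signal = 10,
                             effect = 4, seed = 6)
  sel <- consensus_features(fs, k = 10)
  res <- loocv_classify(fs, sel)
  expect_equal(res$overall_accuracy, 1)
  expect_equal(res$overall_accuracy,
               (res$specificity + res$sensitivity) / 2)
  # swapping group labels swaps the roles but not the overall accuracy
  flipped <- labeled_feature_set(fs$features,
                                 ifelse(fs$labels == "groupA", "z_b", "a_a"))
  res2 <- loocv_classify(flipped, sel$consensus)
  expect_equal(res2$overall_accuracy, res$overall_accuracy)
  expect_error(loocv_classify(fs, integer(0)), "empty")
})

test_that("the compiled linear SVM agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (case in 1:3) {
    n <- 30
    X <- rbind(matrix(rnorm(n / 2 * 5, 1.5), n / 2),
               matrix(rnorm(n / 2 * 5, -1.5), n / 2))
    y <- rep(c(1L, 0L), each = n / 2)
    fit <- cpp_svm_train(X, y, 1)
    dec <- X %*% fit$w + fit$b
    ref <- e1071::svm(X, factor(y, levels = 0:1), kernel = "linear",
                      cost = 1, scale = FALSE)
    expect_gte(mean((dec > 0) == (predict(ref, X) == 1)), 0.95)
    # and the Gram-based LOOCV path predicts the same labels as refitting
    pred_gram <- cpp_svm_loocv(X, y, 1)
    pred_ref <- vapply(seq_len(n), function(m) {
      f <- e1071::svm(X[-m, ], factor(y[-m], levels = 0:1),
                      kernel = "linear", cost = 1, scale = FALSE)
      as.integer(predict(f, X[m, , drop = FALSE]) == 1)
    }, 0L)
    expect_gte(mean(pred_gram == pred_ref), 0.9)
  }
})

test_that("consensus-fixed accuracy is optimistic under the null; nested is not", {
  # the consensus intersection conditions every retained feature on high
  # rank correlation with labels that include each held-out subject, so the
  # fixed-consensus LOOCV cannot be read as an absolute accuracy: it needs
  # its permutation null. The nested estimator stays at chance.
  fs <- make_signal_features(n_per_group = 40, p = 990, n_signal = 0, seed = 8)
  sel <- consensus_features(fs, k = 200)
  biased <- loocv_classify(fs, sel)$overall_accuracy
  honest <- nested_loocv_classify(fs, k = 200)$overall_accuracy
  expect_gt(biased, 0.7)
  expect_lt(abs(honest - 0.5), 0.2)
})

test_that("permutation p uses the add-one estimator and is reproducible", {
  fs <- make_signal_features(n_per_group = 6, p = 40, n_signal = 10,
                             effect = 4, seed = 9)
  r1 <- permutation_test_accuracy(fs, k = 10, n_perm = 30, seed = 5)
  r2 <- permutation_test_accuracy(fs, k = 10, n_perm = 30, seed = 5)
  expect_identical(r1$null_accuracy, r2$null_accuracy)
  expect_equal(r1$permutation_p,
               (1 + sum(r1$null_accuracy >= r1$overall_accuracy)) / 31)
  # n_perm = 1 with a null at least as good gives p = 1
  fs0 <- make_signal_features(n_per_group = 4, p = 10, n_signal = 0, seed = 10)
  r0 <- permutation_test_accuracy(fs0, k = 10, n_perm = 1, seed = 1)
  expect_true(r0$permutation_p %in% c(0.5, 1))
  # strongly separable data at realistic size: observed accuracy is perfect
  # and significant against the nested null
  fss <- make_signal_features(n_per_group = 40, p = 200, n_signal = 10,
                              effect = 4, seed = 14)
  rs <- permutation_test_accuracy(fss, k = 50, n_perm = 49, seed = 2)
  expect_equal(rs$overall_accuracy, 1)
  expect_lte(rs$permutation_p, 0.05)
  # non-nested mode runs against the fixed consensus
  rn <- permutation_test_accuracy(fs, k = 10, n_perm = 30, seed = 3,
                                  nested = FALSE)
  expect_length(rn$null_accuracy, 30)
})

test_that("the fixed-selection null accuracy is centred near chance", {
  # leave-one-out trains on 39-vs-40 folds, whose majority pull depresses
  # the null mean a few points below 0.5 (libsvm measures the same ~0.46);
  # the null is near chance, not optimistically shifted
  fs <- make_signal_features(n_per_group = 40, p = 200, n_signal = 0, seed = 11)
  r <- permutation_test_accuracy(fs, k = 50, n_perm = 500, seed = 4,
                                 nested = FALSE)
  expect_lt(abs(mean(r$null_accuracy) - 0.5), 0.05)
  expect_lt(mean(r$null_accuracy), 0.52)
})

test_that("stratified k-fold classification matches LOOCV on strong signal", {
  fs <- make_signal_features(n_per_group = 15, p = 100, n_signal = 10,
                             effect = 3, seed = 12)
  res <- kfold_classify(fs, k = 20, n_folds = 10, seed = 1)
  expect_gte(res$overall_accuracy, 0.9)
})

test_that("classification reports serialize to JSON", {
  fs <- make_signal_features(n_per_group = 6, p = 20, n_signal = 5,
                             effect = 3, seed = 13)
  res <- permutation_test_accuracy(fs, k = 10, n_perm = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_classification_json(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$overall_accuracy, res$overall_accuracy)
  expect_equal(back$n_permutations, 20L)
})
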