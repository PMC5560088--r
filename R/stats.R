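#' Permutation test of a group difference
#'
#' Exchanges group membership at random (preserving group sizes) to build the
#' null distribution of the mean difference, and assigns the observed
#' difference a p value with the add-one estimator
#' `(1 + #(|null| >= |observed|)) / (1 + n_perm)`. Two-sided by default via
#' absolute differences; `alternative = "greater"` counts signed null
#' differences at least as large as the observed one.
#'
#' @param values_a,values_b per-subject metric values of the two groups.
#' @param n_perm number of permutations (default 10000).
#' @param seed seed for the permutation stream.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param metric_name label carried into the result.
#' @return An object of class `group_comparison`: `observed_difference`
#'   (mean of B minus mean of A), `null_differences`, `p_perm`, `n_perm`.
#' @export
permutation_group_test <- function(values_a, values_b, n_perm = 10000,
                                   seed = 1, alternative = c("two.sided", "greater"),
                                   metric_name = "metric") {
  alternative <- match.arg(alternative)
  stop_if_not(length(values_a) >= 1 && length(values_b) >= 1,
              "both groups must be non-empty")
  stop_if_not(is_count(n_perm), "n_perm must be a positive integer")
  na <- length(values_a)
  nb <- length(values_b)
  n <- na + nb
  observed <- mean(values_b) - mean(values_a)
  # the null is drawn from the sorted pool, always sampling the smaller
  # group's indices: the resulting two-sided p is exactly invariant to
  # swapping the group roles, not merely invariant in distribution
  pool <- sort(c(values_a, values_b))
  k <- min(na, nb)
  sgn <- if (na <= nb) -1 else 1 # orient as mean(B) - mean(A)
  set.seed(seed)
  total <- sum(pool)
  null <- vapply(seq_len(n_perm), function(b) {
    ik <- sample.int(n, k)
    sk <- sum(pool[ik])
    sgn * (sk / k - (total - sk) / (n - k))
  }, 0)
  exceed <- if (alternative == "two.sided") sum(abs(null) >= abs(observed))
            else sum(null >= observed)
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(metric_name = metric_name, observed_difference = observed,
                 null_differences = null, p_perm = p,
                 fdr_significant = NA, n_perm = as.integer(n_perm),
                 seed = seed, alternative = alternative),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: difference (B - A) = %.4g, permutation p = %.4g (%d permutations)\n",
              x$metric_name, x$observed_difference, x$p_perm, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `alpha`: the sorted p values are compared with
#' `i/m * alpha` and everything up to the largest passing rank is flagged.
#' Adjusted values are the usual monotone BH q values.
#'
#' @param p_values vector of p values in `(0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `significant` (logical flags) and `adjusted`.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(significant = logical(0), adjusted = numeric(0)))
  stop_if_not(all(p_values > 0 & p_values <= 1), "p values must be in (0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  list(significant = adjusted <= alpha, adjusted = adjusted)
}

#' Covariate-adjusted group ANOVA with effect size
#'
#' Least-squares fit `metric ~ age + diameter + group` with the group term
#' entered last; the sequential F for group therefore tests the group effect
#' adjusted for both covariates, and the classical eta squared is its share
#' of the total sum of squares (`partial = TRUE` instead relates it to
#' group + residual).
#'
#' @param metric per-subject metric values.
#' @param group two-level factor (or coercible).
#' @param age,diameter covariates.
#' @param partial report partial eta squared instead of classical.
#' @param metric_name label carried into the result.
#' @return An object of class `ancova_result` with `f_group`, `df`,
#'   `eta_squared`, `p_value` and the covariate table.
#' @export
ancova_group <- function(metric, group, age, diameter, partial = FALSE,
                         metric_name = "metric") {
  group <- as.factor(group)
  n <- length(metric)
  stop_if_not(n >= 5, "need at least 5 subjects")
  stop_if_not(nlevels(group) == 2, "group must have two levels")
  stop_if_not(all(is.finite(age)) && all(is.finite(diameter)),
              "covariates must be finite")
  if (qr(cbind(1, age, diameter))$rank < 3)
    stop("collinear covariates", call. = FALSE)
  dat <- data.frame(metric = metric, group = group, age = age,
                    diameter = diameter)
  fit <- lm(metric ~ age + diameter + group, data = dat)
  an <- anova(fit)
  ss <- an[, "Sum Sq"]
  names(ss) <- rownames(an)
  ss_group <- ss[["group"]]
  eta2 <- if (partial) ss_group / (ss_group + ss[["Residuals"]])
          else ss_group / sum(ss)
  structure(list(metric_name = metric_name,
                 f_group = an["group", "F value"],
                 df = c(1L, an["Residuals", "Df"]),
                 eta_squared = eta2,
                 p_value = an["group", "Pr(>F)"],
                 covariate_terms = an[c("age", "diameter"), , drop = FALSE],
                 fit = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> %s: F(%d,%d) = %.3f, eta^2 = %.4f, p = %.4g\n",
              x$metric_name, x$df[1], x$df[2], x$f_group, x$eta_squared,
              x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction: `sum((O - E)^2 / E)` on 1 degree of
#' freedom, as used for sex ratios in group descriptives.
#'
#' @param counts 2x2 matrix of nonnegative integers with positive margins.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stop_if_not(all(dim(counts) == c(2, 2)), "counts must be 2x2")
  stop_if_not(all(counts >= 0) && all(counts == floor(counts)),
              "counts must be nonnegative integers")
  stop_if_not(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
              "all row and column totals must be positive")
  stat <- unname(chisq.test(counts, correct = FALSE)$statistic)
  list(statistic = stat, df = 1L, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Pooled two-sample t test from summary statistics
#'
#' The independent-samples t with pooled variance, computable from printed
#' group means, SDs and sizes (so tabulated descriptives can be checked
#' without raw data).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
pooled_t_test <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stop_if_not(n_a >= 2 && n_b >= 2, "need n >= 2 per group")
  stop_if_not(sd_a > 0 || sd_b > 0, "at least one SD must be positive")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_b - mean_a) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Group descriptives for a cohort table
#'
#' Pooled t tests on age and diameter (raw data), mirroring the usual
#' cohort-characteristics table.
#'
#' @param table cohort data.frame with `group`, `age`, `diameter`.
#' @return data.frame with one row per covariate.
#' @export
cohort_descriptives <- function(table) {
  g <- as.factor(table$group)
  lv <- levels(g)
  rows <- lapply(c("age", "diameter"), function(v) {
    a <- table[[v]][g == lv[1]]
    b <- table[[v]][g == lv[2]]
    tt <- pooled_t_test(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    data.frame(variable = v, mean_a = mean(a), sd_a = sd(a),
               mean_b = mean(b), sd_b = sd(b), t = tt$t, df = tt$df,
               p_value = tt$p_value)
  })
  do.call(rbind, rows)
}

#' Group comparison table over the six topology metrics
#'
#' For every integrated metric in a [cohort_profiles()] data.frame: group
#' means and SDs, the permutation p of the group difference, the FDR flag
#' across the six tests, and the covariate-adjusted ANOVA (F, eta squared,
#' p) — the full results layout of the topology arm.
#'
#' @param profiles data.frame from [cohort_profiles()].
#' @param table cohort table with `subject_id`, `group`, `age`, `diameter`.
#' @param n_perm permutations per metric (default 10000).
#' @param seed base seed.
#' @param alpha FDR level.
#' @param alternative sidedness of the permutation test.
#' @return data.frame with one row per metric.
#' @export
group_metric_table <- function(profiles, table, n_perm = 10000, seed = 1,
                               alpha = 0.05,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  metrics <- c("global_efficiency_norm", "local_efficiency_norm",
               "modularity_q", "intramodular_norm", "intermodular_norm",
               "intra_inter_ratio")
  merged <- merge(profiles, table, by = "subject_id", sort = FALSE)
  g <- as.factor(merged$group)
  lv <- levels(g)
  rows <- list()
  for (k in seq_along(metrics)) {
    m <- metrics[k]
    ok <- is.finite(merged[[m]])
    if (any(!ok))
      ht_log(sum(!ok), " subject(s) dropped for ", m, " (metric undefined)")
    a <- merged[[m]][ok & g == lv[1]]
    b <- merged[[m]][ok & g == lv[2]]
    pt <- permutation_group_test(a, b, n_perm = n_perm,
                                 seed = derive_stream_seed(seed, k),
                                 alternative = alternative, metric_name = m)
    av <- ancova_group(merged[[m]][ok], g[ok], merged$age[ok],
                       merged$diameter[ok], metric_name = m)
    rows[[k]] <- data.frame(metric = m,
                            mean_a = mean(a), sd_a = sd(a),
                            mean_b = mean(b), sd_b = sd(b),
                            difference = pt$observed_difference,
                            p_perm = pt$p_perm,
                            f_group = av$f_group,
                            eta_squared = av$eta_squared,
                            p_ancova = av$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  fdr <- fdr_correct(out$p_perm, alpha)
  out$p_perm_adjusted <- fdr$adjusted
  out$fdr_significant <- fdr$significant
  out
}
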