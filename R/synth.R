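#' Block-modular correlation matrix
#'
#' Builds the covariance (here: correlation) matrix of a modular system:
#' unit diagonal, `intra_r` between regions of the same module and `inter_r`
#' between regions of different modules. Matrices of this form are positive
#' semidefinite whenever `0 <= inter_r <= intra_r < 1`; the smallest
#' eigenvalue is nevertheless checked and, if numerically indefinite, the
#' matrix is repaired by clipping negative eigenvalues at zero and rescaling
#' back to a unit diagonal.
#'
#' @param module_sizes integer vector of module sizes; their sum is the matrix
#'   dimension.
#' @param intra_r within-module correlation, in `[0, 1)`.
#' @param inter_r between-module correlation, in `[0, intra_r]`.
#' @return A symmetric positive semidefinite matrix with unit diagonal.
#' @examples
#' make_modular_covariance(c(2, 2), intra_r = 0.6, inter_r = 0.2)
#' @export
make_modular_covariance <- function(module_sizes, intra_r, inter_r) {
  stop_if_not(length(module_sizes) >= 1 && all(vapply(module_sizes, is_count, TRUE)),
              "module_sizes must be positive integers")
  stop_if_not(is_number(intra_r) && intra_r >= 0 && intra_r < 1,
              "intra_r must be in [0, 1)")
  stop_if_not(is_number(inter_r) && inter_r >= 0, "inter_r must be nonnegative")
  stop_if_not(inter_r <= intra_r,
              "inter_r must not exceed intra_r (positive semidefiniteness)")
  n <- sum(module_sizes)
  block <- rep(seq_along(module_sizes), module_sizes)
  sigma <- matrix(inter_r, n, n)
  same <- outer(block, block, "==")
  sigma[same] <- intra_r
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(sigma))
    sigma <- sigma / outer(d, d)
    diag(sigma) <- 1
    ht_log("covariance repaired by eigenvalue clipping (smallest eigenvalue ",
           signif(min(ev$values), 3), ")")
  }
  attr(sigma, "modules") <- block
  sigma
}

#' Configuration of a synthetic two-group cohort
#'
#' Fixes every parameter of the generator: cohort dimensions, the block-modular
#' correlation structure of each group, measurement noise, confound injection,
#' and the covariate distributions. The defaults encode the study conditions
#' this generator emulates: 40 subjects per group, a 45-ROI hemispheric
#' parcellation observed over 301 timepoints at a 1.5 s sampling interval,
#' three 15-ROI modules, and a group contrast in which group A couples less
#' within modules and more between modules than group B (the slow- vs
#' fast-growing-lesion contrast). Ages and lesion diameters default to the
#' group moments of the study population.
#'
#' @param n_per_group subjects per group.
#' @param n_rois regions of interest per subject.
#' @param n_timepoints scan volumes per subject (>= 2).
#' @param tr sampling interval in seconds.
#' @param module_sizes module sizes, summing to `n_rois`.
#' @param intra_r,inter_r length-2 vectors (group A, group B) of within- and
#'   between-module correlations.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param baseline constant signal offset; with unit-variance fluctuations the
#'   temporal signal-to-noise ratio of a clean subject is approximately this
#'   value (default 100, comfortably above the QC gate of 45).
#' @param confound_spec list with `global_amp` (amplitude of a shared global
#'   signal added to every ROI), `drift_amp` (total linear drift over the
#'   scan), `spike_prob` and `spike_amp` (per-timepoint spike probability and
#'   size). All default to 0.
#' @param age_mean,age_sd,diameter_mean,diameter_sd length-2 vectors of
#'   covariate moments (years, millimetres); draws are truncated to ages
#'   18-90 and diameters 5-120 mm.
#' @param seed master seed; every subject derives its own stream from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 40, n_rois = 45, n_timepoints = 301,
                          tr = 1.5, module_sizes = c(15, 15, 15),
                          intra_r = c(groupA = 0.45, groupB = 0.60),
                          inter_r = c(groupA = 0.25, groupB = 0.15),
                          noise_sd = 0, baseline = 100,
                          confound_spec = list(global_amp = 0, drift_amp = 0,
                                               spike_prob = 0, spike_amp = 0),
                          age_mean = c(38.8, 51.3), age_sd = c(10.8, 13.1),
                          diameter_mean = c(55, 48), diameter_sd = c(19, 16),
                          seed = 1) {
  stop_if_not(is_count(n_per_group), "n_per_group must be a positive integer")
  stop_if_not(is_count(n_rois), "n_rois must be a positive integer")
  stop_if_not(is_count(n_timepoints) && n_timepoints >= 2,
              "n_timepoints must be an integer >= 2")
  stop_if_not(is_number(tr) && tr > 0, "tr must be positive")
  stop_if_not(sum(module_sizes) == n_rois, "module_sizes must sum to n_rois")
  intra_r <- rep_len(unname(intra_r), 2)
  inter_r <- rep_len(unname(inter_r), 2)
  for (g in 1:2) {
    stop_if_not(intra_r[g] >= 0 && intra_r[g] < 1, "intra_r must be in [0, 1)")
    stop_if_not(inter_r[g] >= 0 && inter_r[g] <= intra_r[g],
                "each group needs 0 <= inter_r <= intra_r")
  }
  stop_if_not(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be nonnegative")
  spec <- list(global_amp = 0, drift_amp = 0, spike_prob = 0, spike_amp = 0)
  spec[names(confound_spec)] <- confound_spec
  stop_if_not(spec$spike_prob >= 0 && spec$spike_prob <= 1,
              "spike_prob must be a probability")
  cfg <- list(n_per_group = n_per_group, n_rois = n_rois,
              n_timepoints = n_timepoints, tr = tr,
              module_sizes = module_sizes, intra_r = intra_r, inter_r = inter_r,
              noise_sd = noise_sd, baseline = baseline, confound_spec = spec,
              age_mean = rep_len(age_mean, 2), age_sd = rep_len(age_sd, 2),
              diameter_mean = rep_len(diameter_mean, 2),
              diameter_sd = rep_len(diameter_sd, 2), seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Simulate one subject
#'
#' Draws a timepoints-by-ROI panel as independent multivariate-normal samples
#' from the group's block-modular correlation matrix, then adds measurement
#' noise, the configured confounds (shared global signal, linear drift,
#' spikes) and the baseline offset. Injected confounds are stored as regressor
#' columns of the panel so the denoising stage can remove them. Timepoints are
#' temporally white by design: all downstream analyses operate on correlation
#' matrices, for which white generation is sufficient and analytically
#' checkable.
#'
#' @param cfg a [cohort_config()].
#' @param group `"groupA"` or `"groupB"`.
#' @param rng_seed integer seed for this subject's stream.
#' @param subject_id optional id string.
#' @return A `subject_record`: list with `subject_id`, `group`, `age`,
#'   `diameter` and `panel` (a [time_series_panel()]).
#' @export
simulate_subject <- function(cfg, group, rng_seed, subject_id = NULL) {
  stop_if_not(inherits(cfg, "cohort_config"), "cfg must be a cohort_config")
  stop_if_not(group %in% c("groupA", "groupB"), "group must be groupA or groupB")
  g <- if (group == "groupA") 1L else 2L
  set.seed(rng_seed)
  tp <- cfg$n_timepoints
  sigma <- make_modular_covariance(cfg$module_sizes, cfg$intra_r[g], cfg$inter_r[g])
  ev <- eigen(sigma, symmetric = TRUE)
  rot <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  x <- matrix(rnorm(tp * cfg$n_rois), tp, cfg$n_rois) %*% rot
  if (cfg$noise_sd > 0) x <- x + matrix(rnorm(tp * cfg$n_rois, sd = cfg$noise_sd),
                                        tp, cfg$n_rois)
  spec <- cfg$confound_spec
  confounds <- NULL
  if (spec$global_amp > 0) {
    gsig <- rnorm(tp)
    x <- x + spec$global_amp * gsig
    confounds <- cbind(confounds, global_signal = gsig)
  }
  if (spec$drift_amp != 0) {
    drift <- seq(-0.5, 0.5, length.out = tp)
    x <- x + spec$drift_amp * drift
    confounds <- cbind(confounds, linear_drift = drift)
  }
  if (spec$spike_prob > 0) {
    spikes <- as.numeric(runif(tp) < spec$spike_prob)
    x <- x + spec$spike_amp * spikes
    confounds <- cbind(confounds, spike = spikes)
  }
  x <- x + cfg$baseline
  age <- rtruncnorm1(cfg$age_mean[g], cfg$age_sd[g], 18, 90)
  diameter <- rtruncnorm1(cfg$diameter_mean[g], cfg$diameter_sd[g], 5, 120)
  id <- subject_id %||% sprintf("subj_%s_%d", group, rng_seed)
  panel <- time_series_panel(x, tr = cfg$tr,
                             roi_names = default_roi_names(cfg$n_rois),
                             confounds = confounds, subject_id = id)
  out <- list(subject_id = id, group = group, age = age, diameter = diameter,
              panel = panel)
  class(out) <- "subject_record"
  out
}

#' Simulate a two-group cohort
#'
#' Generates `2 * n_per_group` subjects with the configured group contrast.
#' One master seed spawns a private stream per subject (counter-based), so
#' cohorts are reproducible as a whole while subjects stay independent.
#'
#' @param cfg a [cohort_config()].
#' @return A `cohort`: list with `subjects` (list of `subject_record`) and
#'   `table` (data.frame: subject_id, group, age, diameter).
#' @export
simulate_cohort <- function(cfg) {
  stop_if_not(inherits(cfg, "cohort_config"), "cfg must be a cohort_config")
  groups <- rep(c("groupA", "groupB"), each = cfg$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(cfg, groups[i],
                                      rng_seed = derive_stream_seed(cfg$seed, i),
                                      subject_id = ids[i])
  }
  tab <- data.frame(subject_id = ids, group = groups,
                    age = vapply(subjects, `[[`, 0, "age"),
                    diameter = vapply(subjects, `[[`, 0, "diameter"),
                    stringsAsFactors = FALSE)
  out <- list(subjects = subjects, table = tab, config = cfg)
  class(out) <- "cohort"
  out
}

#' Write a cohort to disk
#'
#' One TSV per subject (header row of ROI names, one row per timepoint, with
#' confound regressors in a sibling `*_confounds.tsv` when present), a cohort
#' CSV (subject_id, group, age, diameter, path) and a YAML echo of the
#' generating configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The cohort table with the `path` column, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stop_if_not(inherits(cohort, "cohort"), "cohort must be a cohort object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    paths[i] <- file.path(dir, paste0(s$subject_id, ".tsv"))
    write_panel_tsv(s$panel, paths[i])
  }
  tab <- cohort$table
  tab$path <- paths
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg_list <- unclass(cfg)
  cfg_list$module_sizes <- as.integer(cfg_list$module_sizes)
  yaml::write_yaml(cfg_list, file.path(dir, "cohort_config.yaml"))
  invisible(tab)
}
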