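#' Pipeline configuration
#'
#' One object fixing every stage of the end-to-end analysis: input/output
#' paths, connectivity settings, classification settings, network settings
#' and group-statistics settings. Every seed is explicit; rerunning an
#' identical configuration reproduces identical outputs.
#'
#' @param output_dir run directory for all artifacts.
#' @param cohort_table path to a cohort CSV (subject_id, group, age,
#'   diameter, path) whose `path` column points to time-series TSVs; `NULL`
#'   to simulate instead.
#' @param tr sampling interval used when reading TSV panels.
#' @param simulate a [cohort_config()] used when `cohort_table` is `NULL`.
#' @param low_hz,high_hz band-pass edges.
#' @param tsnr_threshold QC gate.
#' @param k,class_n_perm,class_seed,cost,nested,cv classification settings
#'   (`cv = "loo"` or a fold count).
#' @param grid a [sparsity_grid()].
#' @param n_nulls,n_runs,network_seed,swaps_per_edge network settings.
#' @param stats_n_perm,alpha,alternative,stats_seed group-statistics settings.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            cohort_table = NULL, tr = 1.5,
                            simulate = cohort_config(),
                            low_hz = 0.009, high_hz = 0.8, tsnr_threshold = 45,
                            k = 200, class_n_perm = 10000, class_seed = 1,
                            cost = 1, nested = TRUE, cv = "loo",
                            grid = sparsity_grid(), n_nulls = 1000,
                            n_runs = 100, network_seed = 1, swaps_per_edge = 10,
                            stats_n_perm = 10000, alpha = 0.05,
                            alternative = "two.sided", stats_seed = 1) {
  stop_if_not(is.character(output_dir) && length(output_dir) == 1,
              "output_dir must be a path")
  if (!is.null(cohort_table))
    stop_if_not(file.exists(cohort_table), "cohort_table does not exist: ",
                cohort_table)
  cfg <- list(output_dir = output_dir, cohort_table = cohort_table, tr = tr,
              simulate = simulate, low_hz = low_hz, high_hz = high_hz,
              tsnr_threshold = tsnr_threshold, k = k,
              class_n_perm = class_n_perm, class_seed = class_seed,
              cost = cost, nested = nested, cv = cv, grid = grid,
              n_nulls = n_nulls, n_runs = n_runs,
              network_seed = network_seed, swaps_per_edge = swaps_per_edge,
              stats_n_perm = stats_n_perm, alpha = alpha,
              alternative = alternative, stats_seed = stats_seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the [pipeline_config()] fields;
#'   `simulate` may itself be a mapping of [cohort_config()] fields and
#'   `grid` a list of sparsity levels.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(cohort_config, y$simulate)
  if (!is.null(y$grid)) y$grid <- sparsity_grid(unlist(y$grid))
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  # stable fingerprint stamped into every artifact
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> connectivity -> classification -> network
#' topology -> group statistics, writing every artifact into the run
#' directory: per-subject time series (when simulated), connectivity
#' matrices and feature CSVs, a JSON classification report, per-subject
#' metric CSV, the group results table, QC exclusions, and a YAML echo of
#' the configuration stamped with its hash. Any stage failure halts with a
#' stage-named error; QC-failed subjects are excluded and listed.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the main results and artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stop_if_not(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(cfg))
  echo <- unclass(cfg)
  echo$simulate <- unclass(echo$simulate)
  echo$grid <- echo$grid$levels
  yaml::write_yaml(c(stamp, echo), file.path(out, "config_echo.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## stage: cohort (simulate or load)
  cohort <- stage("cohort", {
    if (is.null(cfg$cohort_table)) {
      ch <- simulate_cohort(cfg$simulate)
      write_cohort(ch, file.path(out, "timeseries"))
      list(table = ch$table,
           panels = lapply(ch$subjects, `[[`, "panel"))
    } else {
      tab <- read.csv(cfg$cohort_table, stringsAsFactors = FALSE)
      panels <- lapply(seq_len(nrow(tab)), function(i)
        read_panel_tsv(tab$path[i], tr_read = cfg$tr,
                       subject_id = tab$subject_id[i]))
      list(table = tab[, c("subject_id", "group", "age", "diameter")],
           panels = panels)
    }
  })

  ## stage: connectivity (QC gate + denoise + correlate)
  conn <- stage("connectivity", {
    dir.create(file.path(out, "connectivity"), showWarnings = FALSE)
    matrices <- list()
    excluded <- character(0)
    for (i in seq_len(nrow(cohort$table))) {
      id <- cohort$table$subject_id[i]
      cm <- panel_connectivity(cohort$panels[[i]], cfg$low_hz, cfg$high_hz,
                               cfg$tsnr_threshold)
      if (is.null(cm)) {
        excluded <- c(excluded, id)
      } else {
        matrices[[id]] <- cm
        write_connectivity_csv(cm, file.path(out, "connectivity",
                                             paste0(id, ".csv")))
      }
    }
    writeLines(excluded, file.path(out, "excluded_subjects.txt"))
    list(matrices = matrices, excluded = excluded)
  })
  table <- cohort$table[!cohort$table$subject_id %in% conn$excluded, ]
  if (length(conn$excluded))
    ht_log("excluded ", length(conn$excluded), " subject(s) at QC: ",
           paste(conn$excluded, collapse = ", "))

  ## stage: classification
  class_res <- stage("classify", {
    fset <- feature_set_from_matrices(conn$matrices[table$subject_id], table)
    dir.create(file.path(out, "features"), showWarnings = FALSE)
    for (id in table$subject_id)
      write_feature_csv(vectorize_upper_triangle(conn$matrices[[id]]),
                        file.path(out, "features", paste0(id, ".csv")))
    res <- if (identical(cfg$cv, "loo")) {
      permutation_test_accuracy(fset, k = cfg$k, n_perm = cfg$class_n_perm,
                                seed = cfg$class_seed, cost = cfg$cost,
                                nested = cfg$nested)
    } else {
      kfold_classify(fset, k = cfg$k, n_folds = as.integer(cfg$cv),
                     seed = cfg$class_seed, cost = cfg$cost)
    }
    write_classification_json(res, file.path(out, "classification.json"),
                              index_map = fset$index_map)
    res
  })

  ## stage: network topology
  profiles <- stage("network", {
    pr <- cohort_profiles(conn$matrices[table$subject_id], grid = cfg$grid,
                          n_nulls = cfg$n_nulls, n_runs = cfg$n_runs,
                          seed = cfg$network_seed,
                          swaps_per_edge = cfg$swaps_per_edge,
                          partitions_dir = file.path(out, "partitions"))
    write_metric_csv(pr, file.path(out, "metrics.csv"))
    pr
  })

  ## stage: group statistics
  results <- stage("stats", {
    tab <- group_metric_table(profiles, table, n_perm = cfg$stats_n_perm,
                              seed = cfg$stats_seed, alpha = cfg$alpha,
                              alternative = cfg$alternative)
    write.csv(tab, file.path(out, "group_results.csv"), row.names = FALSE)
    desc <- cohort_descriptives(table)
    write.csv(desc, file.path(out, "descriptives.csv"), row.names = FALSE)
    list(metrics = tab, descriptives = desc)
  })

  invisible(list(table = table, excluded = conn$excluded,
                 classification = class_res, profiles = profiles,
                 group_results = results$metrics,
                 descriptives = results$descriptives,
                 output_dir = out))
}
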