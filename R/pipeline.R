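# End-to-end orchestration: simulate (or read) -> preprocess -> classify
# (three tasks) -> explain -> stats, with all outputs written as CSV/JSON
# and listed in a run manifest.

#' Configuration of a full pipeline run
#'
#' Collects the per-stage settings of [run_pipeline()] into one list.  Any
#' field can be overridden; defaults reproduce the standard study design.
#'
#' @param cohort a [cohort_config()]; ignored when `raw_dir` is given.
#' @param raw_dir optional directory of an existing raw dataset (as written
#'   by [write_grf_dataset()]); when set, the simulate stage is skipped.
#' @param cutoff,threshold,n_points preprocessing settings.
#' @param tasks classification tasks to run.
#' @param k outer folds.
#' @param grid `C` grid for the grid search.
#' @param group_by relevance aggregation grouping(s).
#' @param alpha,n_perm SPM settings.
#' @param seed seed for folds, solver and permutations.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), raw_dir = NULL,
                            cutoff = 50, threshold = 10, n_points = 101,
                            tasks = c("subject_x_footwear", "subject",
                                      "footwear"),
                            k = 4, grid = c_grid(),
                            group_by = c("task", "class"),
                            alpha = 0.05, n_perm = 1000, seed = 1L) {
  structure(list(cohort = cohort, raw_dir = raw_dir, cutoff = cutoff,
                 threshold = threshold, n_points = n_points, tasks = tasks,
                 k = k, grid = grid, group_by = group_by, alpha = alpha,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `cohort:` block maps onto [cohort_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, raw$cohort %||% list())
  args <- raw[setdiff(names(raw), "cohort")]
  do.call(pipeline_config, c(list(cohort = cohort), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete analysis pipeline
#'
#' Executes simulate (or read) -> preprocess -> classify (one [run_task()]
#' per requested task) -> explain ([relevance_scores()] +
#' [aggregate_relevance()]) -> stats ([spm_anova()] per channel,
#' [discrete_variables()], [kruskal_wallis()] and [dscf_posthoc()] per
#' discrete variable).  All tabular outputs are written under `out_dir`
#' and listed, together with seeds and configuration, in
#' `manifest.json`.  Rerunning with the same configuration reproduces all
#' numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all in-memory stage results and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  # -- simulate / ingest ----------------------------------------------------
  dataset <- if (!is.null(config$raw_dir)) {
    if (!dir.exists(config$raw_dir))
      stop("raw data directory not found: ", config$raw_dir, call. = FALSE)
    read_grf_dataset(config$raw_dir)
  } else generate_dataset(config$cohort)
  emit("metadata.csv", function(p) write.csv(dataset$metadata, p,
                                             row.names = FALSE))
  message(sprintf("[simulate] %d recordings", nrow(dataset$metadata)))

  # -- preprocess -----------------------------------------------------------
  prep <- preprocess_dataset(dataset, cutoff = config$cutoff,
                             threshold = config$threshold,
                             n_points = config$n_points)
  emit("features.csv", function(p) {
    df <- cbind(dataset$metadata[c("subject_id", "footwear_id", "trial_id")],
                as.data.frame(prep$features))
    write.csv(df, p, row.names = FALSE)
  })
  message(sprintf("[preprocess] %d x %d feature matrix",
                  nrow(prep$features), ncol(prep$features)))

  # -- classify -------------------------------------------------------------
  cvs <- list()
  for (task in config$tasks) {
    cv <- run_task(task, prep$features, prep$metadata, k = config$k,
                   seed = config$seed, grid = config$grid)
    cvs[[task]] <- cv
    emit(paste0("cv_", task, ".json"), function(p)
      jsonlite::write_json(list(
        task = cv$task, fold_accuracy = cv$fold_accuracy,
        median_accuracy = cv$median_accuracy,
        mean_accuracy = cv$mean_accuracy, selected_C = cv$selected_C,
        zero_rule_baseline = cv$baseline, seed = config$seed
      ), p, auto_unbox = TRUE, digits = NA))
    emit(paste0("confusion_", task, ".csv"), function(p)
      write.csv(as.data.frame.matrix(cv$confusion), p))
    emit(paste0("posthoc_", task, ".csv"), function(p)
      write.csv(data.frame(
        group = c(names(cv$accuracy_by_subject),
                  names(cv$accuracy_by_footwear)),
        kind = c(rep("subject", length(cv$accuracy_by_subject)),
                 rep("footwear", length(cv$accuracy_by_footwear))),
        accuracy = c(cv$accuracy_by_subject, cv$accuracy_by_footwear)
      ), p, row.names = FALSE))
    message(sprintf("[classify] %s: median accuracy %.1f%% (baseline %.1f%%)",
                    task, 100 * cv$median_accuracy, 100 * cv$baseline))
  }

  # -- explain --------------------------------------------------------------
  aggregates <- list()
  for (task in names(cvs)) {
    rel <- relevance_scores(cvs[[task]], prep$features, prep$metadata)
    for (gb in config$group_by) {
      agg <- aggregate_relevance(rel, group_by = gb,
                                 features = prep$features)
      aggregates[[paste(task, gb, sep = ".")]] <- agg
      emit(paste0("relevance_", task, "_", gb, ".json"), function(p)
        jsonlite::write_json(lapply(agg$groups, function(g)
          list(channel_totals = as.list(g$channel_totals), n = g$n)),
          p, auto_unbox = TRUE, digits = NA))
    }
    message(sprintf("[explain] %s: %d relevance maps", task,
                    nrow(rel$scores)))
  }

  # -- stats ----------------------------------------------------------------
  channels <- c(ml = 1, ap = 2, v = 3)
  np <- config$n_points
  spm <- lapply(names(channels), function(ch) {
    cols <- (channels[[ch]] - 1) * np + seq_len(np)
    spm_anova(prep$features[, cols], prep$metadata$footwear_id,
              alpha = config$alpha, n_perm = config$n_perm,
              seed = config$seed)
  })
  names(spm) <- names(channels)
  emit("spm.json", function(p)
    jsonlite::write_json(lapply(spm, function(s)
      list(f_crit = s$f_crit, clusters = s$clusters, F = s$F)),
      p, auto_unbox = TRUE, digits = NA))

  disc <- discrete_variables(prep$curves)
  emit("discrete_variables.csv", function(p)
    write.csv(disc, p, row.names = FALSE))
  vars <- setdiff(names(disc), c("subject_id", "footwear_id", "trial_id"))
  tests <- do.call(rbind, lapply(vars, function(v) {
    kw <- kruskal_wallis(disc[[v]], disc$footwear_id)
    data.frame(variable = v, H = kw$H, df = kw$df, p = kw$p)
  }))
  emit("kruskal_wallis.csv", function(p)
    write.csv(tests, p, row.names = FALSE))
  posthoc <- lapply(vars[tests$p < config$alpha & !is.na(tests$p)],
                    function(v) dscf_posthoc(disc[[v]], disc$footwear_id))
  names(posthoc) <- vars[tests$p < config$alpha & !is.na(tests$p)]
  emit("dscf_posthoc.json", function(p)
    jsonlite::write_json(lapply(posthoc, function(x)
      list(p = as.data.frame(x$p), W = as.data.frame(x$W))),
      p, auto_unbox = TRUE, digits = NA))
  message(sprintf("[stats] %d discrete variables, %d with significant KW test",
                  length(vars), length(posthoc)))

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitsig")),
    seed = config$seed,
    cohort_seed = if (is.null(config$raw_dir)) config$cohort$rng_seed else NA,
    n_recordings = nrow(dataset$metadata),
    settings = list(cutoff = config$cutoff, threshold = config$threshold,
                    n_points = config$n_points, k = config$k,
                    grid_range = range(config$grid),
                    grid_size = length(config$grid),
                    alpha = config$alpha, n_perm = config$n_perm),
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, preprocessed = prep, cv = cvs,
                 relevance = aggregates, spm = spm, discrete = disc,
                 kruskal_wallis = tests, dscf = posthoc,
                 manifest = manifest))
}
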