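#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one object. All
#' stochastic stages derive their seeds from the single master `seed`
#' (cohort simulation uses `seed`, metric nulls `seed + 1`, permutation
#' inference `seed + 2`), so stages are independently rerunnable.
#'
#' @param cohort A [cohort_spec()] used when simulating (ignored when
#'   `input_dir` is given).
#' @param input_dir Optional directory with time-series TSVs and a
#'   `clinical.csv`, as written by a previous run; when given, simulation
#'   is skipped.
#' @param grid A [sparsity_grid()].
#' @param n_nulls Null networks per graph for gamma/lambda/sigma.
#' @param n_runs Community-detection restarts per graph.
#' @param n_perm Permutations for group inference.
#' @param alpha Nominal significance level.
#' @param entry_p,removal_p Stepwise logistic thresholds.
#' @param degree_sparsity Sparsity at which per-subject degree
#'   distributions are extracted for the group distribution comparison
#'   (default 0.22, the sweep midpoint).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            input_dir = NULL,
                            grid = sparsity_grid(),
                            n_nulls = 100,
                            n_runs = 10,
                            n_perm = 10000,
                            alpha = 0.05,
                            entry_p = 0.05,
                            removal_p = 0.10,
                            degree_sparsity = 0.22,
                            seed = 1L) {
  stopifnot(n_nulls >= 1, n_perm >= 100, alpha > 0, alpha < 1,
            entry_p > 0, entry_p < 1, removal_p >= entry_p,
            degree_sparsity > 0, degree_sparsity < 1)
  structure(list(cohort = cohort, input_dir = input_dir, grid = grid,
                 n_nulls = as.integer(n_nulls), n_runs = as.integer(n_runs),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 entry_p = entry_p, removal_p = removal_p,
                 degree_sparsity = degree_sparsity, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file onto [pipeline_config()] / [cohort_spec()] /
#' [sparsity_grid()]. Recognized top-level keys mirror the
#' [pipeline_config()] arguments, with the grid given as `sparsity_min`,
#' `sparsity_max`, `sparsity_step` and the cohort under a `cohort` mapping
#' whose keys mirror [cohort_spec()] (group-dependent correlations as
#' two-element mappings with keys `responder` / `nonresponder`).
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  grid <- sparsity_grid(raw$sparsity_min %||% 0.10,
                        raw$sparsity_max %||% 0.34,
                        raw$sparsity_step %||% 0.01)
  cohort_args <- raw$cohort %||% list()
  for (nm in c("within_module_r", "between_module_r")) {
    if (!is.null(cohort_args[[nm]])) cohort_args[[nm]] <- unlist(cohort_args[[nm]])
  }
  cohort <- do.call(cohort_spec, cohort_args)
  args <- raw[intersect(names(raw), c("input_dir", "n_nulls", "n_runs", "n_perm",
                                      "alpha", "entry_p", "removal_p",
                                      "degree_sparsity", "seed"))]
  do.call(pipeline_config, c(list(cohort = cohort, grid = grid), args))
}

# ---- I/O suite ------------------------------------------------------------

#' Time-series, clinical-table and matrix I/O
#'
#' Plain-text artifact formats used by the pipeline: per-subject time
#' series as TSV (timepoints x ROIs with a header row of ROI labels, one
#' file `<subject_id>.tsv` per subject), the clinical table as CSV with
#' columns `subject_id`, `group`, `age`, `sex`, `hamd17_pre`,
#' `hamd17_post`, `hama_pre`, `hama_post`, and connectivity matrices as
#' N x N CSV with an ROI-label header row and column. All numeric output
#' round-trips exactly (shortest-representation doubles).
#'
#' @param ts,fc,clinical Objects to write.
#' @param path,dir File / directory paths.
#' @param subject_id Identifier (defaults to the object's attribute).
#' @name pipeline_io
NULL

# full-precision double formatting so numeric artifacts round-trip exactly
format_full <- function(d) {
  dplyr::mutate(d, dplyr::across(dplyr::where(is.double),
                                 function(x) sprintf("%.17g", x)))
}

#' @rdname pipeline_io
#' @export
write_timeseries_tsv <- function(ts, path) {
  d <- tibble::as_tibble(as.data.frame(unclass(ts)))
  readr::write_tsv(format_full(d), path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL) {
  # base parser: exact strtod round-trip of the %.17g representation
  d <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(d)
  storage.mode(x) <- "double"
  attr(x, "subject_id") <- subject_id %||%
    sub("\\.tsv$", "", basename(path))
  x
}

#' @rdname pipeline_io
#' @param clinical_tbl Optional clinical table; when given, the files found
#'   must match its `subject_id` column exactly, and orphans on either side
#'   are an error.
#' @export
read_timeseries_dir <- function(dir, clinical_tbl = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  ids <- sub("\\.tsv$", "", basename(files))
  if (!is.null(clinical_tbl)) {
    missing_ts <- setdiff(clinical_tbl$subject_id, ids)
    orphan_ts <- setdiff(ids, clinical_tbl$subject_id)
    if (length(missing_ts) > 0 || length(orphan_ts) > 0) {
      stop(sprintf(
        "time-series / clinical mismatch%s%s",
        if (length(missing_ts)) paste0("; missing time series for: ",
                                       paste(missing_ts, collapse = ", ")) else "",
        if (length(orphan_ts)) paste0("; clinical rows absent for: ",
                                      paste(orphan_ts, collapse = ", ")) else ""),
        call. = FALSE)
    }
  }
  ts <- purrr::map2(files, ids, read_timeseries_tsv)
  names(ts) <- ids
  ts
}

clinical_schema <- c("subject_id", "group", "age", "sex",
                     "hamd17_pre", "hamd17_post", "hama_pre", "hama_post")

#' @rdname pipeline_io
#' @export
write_clinical_csv <- function(clinical, path) {
  readr::write_csv(clinical[, intersect(c(clinical_schema,
                                          "reduction_rate", "responder"),
                                        names(clinical))],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_clinical_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(clinical_schema, names(d))
  if (length(missing_cols) > 0) {
    stop(sprintf("clinical table lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d$group <- factor(d$group, levels = c("responder", "nonresponder"))
  d$sex <- factor(d$sex, levels = c("male", "female"))
  label_responders(d)
}

#' @rdname pipeline_io
#' @export
write_connectivity_csv <- function(fc, path) {
  d <- tibble::as_tibble(as.data.frame(unclass(fc)))
  d <- dplyr::bind_cols(tibble::tibble(roi = rownames(fc)), d)
  readr::write_csv(format_full(d), path, progress = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_connectivity_csv <- function(path, subject_id = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  attr(m, "subject_id") <- subject_id
  m
}

# ---- orchestration --------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes every stage in order — cohort (simulated or read from disk),
#' connectivity, sparsity-swept metrics with AUC integration, permutation
#' group comparison with FDR for nodal metrics, degree / link-weight
#' distribution tests, age- and sex-adjusted partial correlations with
#' symptom change, forward likelihood-ratio logistic prediction of
#' responder status and ROC characterization — persisting every
#' intermediate artifact under `output_dir` and returning a run report.
#' Identical config and seed give identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_report` (list) with the config echo, per-stage record
#'   counts, the global and nodal comparison tables, distribution tests,
#'   correlation table, selected logistic model and ROC summaries.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = tempfile("fcr_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[%s] ", fmt),
                                                        format(Sys.time(), "%H:%M:%S"), ...))

  # stage 1: cohort
  if (is.null(config$input_dir)) {
    say("simulate: generating cohort (seed %d)", config$seed)
    spec <- config$cohort
    spec$seed <- config$seed
    cohort <- simulate_cohort(spec)
  } else {
    say("load: reading cohort from %s", config$input_dir)
    clinical <- read_clinical_csv(file.path(config$input_dir, "clinical.csv"))
    ts <- read_timeseries_dir(config$input_dir, clinical)
    cohort <- structure(list(time_series = ts, clinical = clinical,
                             ground_truth = NULL), class = "fc_cohort")
  }
  clinical <- cohort$clinical
  ts_dir <- file.path(output_dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  purrr::iwalk(cohort$time_series, function(m, id) {
    write_timeseries_tsv(m, file.path(ts_dir, paste0(id, ".tsv")))
  })
  write_clinical_csv(clinical, file.path(output_dir, "clinical.csv"))

  # stage 2: connectivity
  say("connect: %d x %d connectivity for %d subjects",
      ncol(cohort$time_series[[1]]), ncol(cohort$time_series[[1]]),
      nrow(clinical))
  fc_list <- purrr::map(cohort$time_series, compute_fc_matrix)
  fc_dir <- file.path(output_dir, "connectivity")
  dir.create(fc_dir, showWarnings = FALSE)
  purrr::iwalk(fc_list, function(m, id) {
    write_connectivity_csv(m, file.path(fc_dir, paste0(id, ".csv")))
  })

  # stage 3: metrics + AUC
  say("metrics: %d thresholds, %d nulls per graph", length(config$grid),
      config$n_nulls)
  auc_tbl <- cohort_metrics(cohort, grid = config$grid,
                            n_nulls = config$n_nulls, n_runs = config$n_runs,
                            seed = config$seed + 1L, fc_list = fc_list)
  readr::write_csv(auc_tbl, file.path(output_dir, "auc_metrics.csv"),
                   progress = FALSE)

  # stage 4: group inference
  say("compare: permutation tests (%d permutations)", config$n_perm)
  comparison <- compare_group_metrics(auc_tbl, n_perm = config$n_perm,
                                      seed = config$seed + 2L,
                                      alpha = config$alpha)
  global_tbl <- dplyr::filter(comparison, .data$scope == "global")
  nodal_tbl <- dplyr::filter(comparison, .data$scope == "nodal")
  readr::write_csv(global_tbl, file.path(output_dir, "global_comparison.csv"),
                   progress = FALSE)
  readr::write_csv(nodal_tbl, file.path(output_dir, "nodal_comparison.csv"),
                   progress = FALSE)

  say("compare: degree and link-weight distributions")
  by_group <- split(clinical$subject_id, clinical$group)
  degrees <- purrr::map(fc_list, function(fc) {
    degree_distribution(binarize_at_sparsity(fc, config$degree_sparsity))
  })
  weights <- purrr::map(fc_list, link_weight_distribution)
  pooled <- function(lst, ids) unlist(lst[ids], use.names = FALSE)
  dist_tests <- dplyr::bind_rows(
    dplyr::mutate(compare_distributions(pooled(degrees, by_group[[1]]),
                                        pooled(degrees, by_group[[2]])),
                  distribution = "degree", .before = 1),
    dplyr::mutate(compare_distributions(pooled(weights, by_group[[1]]),
                                        pooled(weights, by_group[[2]])),
                  distribution = "link_weight", .before = 1))
  readr::write_csv(dist_tests, file.path(output_dir, "distribution_tests.csv"),
                   progress = FALSE)

  # stage 5: clinical models
  say("clinical: partial correlations and forward-LR logistic model")
  clinical <- dplyr::mutate(clinical,
                            delta_hamd = .data$hamd17_pre - .data$hamd17_post,
                            sex01 = as.integer(.data$sex == "female"))
  sig <- dplyr::filter(comparison, .data$significant)
  feature_keys <- comparison |>
    dplyr::mutate(key = ifelse(.data$scope == "global", .data$metric,
                               paste(.data$metric, .data$node, sep = ":")))
  auc_wide <- auc_tbl |>
    dplyr::mutate(key = ifelse(.data$scope == "global", .data$metric,
                               paste(.data$metric, .data$node, sep = ":"))) |>
    dplyr::select("subject_id", "key", "auc") |>
    tidyr::pivot_wider(names_from = "key", values_from = "auc")
  auc_wide <- auc_wide[match(clinical$subject_id, auc_wide$subject_id), ]
  covar <- cbind(age = clinical$age, sex = clinical$sex01)
  sig_keys <- feature_keys$key[feature_keys$significant]
  corr_keys <- unique(c(feature_keys$key[feature_keys$scope == "global"], sig_keys))
  correlations <- purrr::map_dfr(corr_keys, function(k) {
    dplyr::bind_rows(
      dplyr::mutate(partial_correlation(auc_wide[[k]], clinical$delta_hamd, covar),
                    feature = k, outcome = "delta_hamd17", .before = 1),
      dplyr::mutate(partial_correlation(auc_wide[[k]], clinical$hamd17_pre, covar),
                    feature = k, outcome = "hamd17_pre", .before = 1))
  })
  readr::write_csv(correlations, file.path(output_dir, "partial_correlations.csv"),
                   progress = FALSE)

  nodal_sig_keys <- feature_keys$key[feature_keys$significant &
                                       feature_keys$scope == "nodal"]
  model <- NULL
  model_note <- NULL
  rocs <- list()
  if (length(nodal_sig_keys) > 0) {
    feats <- as.matrix(auc_wide[, nodal_sig_keys, drop = FALSE])
    labels <- clinical$group == "responder"
    # a perfectly separating feature is an informative outcome at cohort
    # scale, not a pipeline failure: note it and skip the model stage
    model <- tryCatch(
      forward_lr_logistic(feats, labels, entry_p = config$entry_p,
                          removal_p = config$removal_p),
      error = function(e) {
        if (!grepl("separation", conditionMessage(e))) stop(e)
        model_note <<- conditionMessage(e)
        say("clinical: %s; skipping logistic model", model_note)
        NULL
      })
  }
  if (!is.null(model)) {
    readr::write_csv(tidy(model), file.path(output_dir, "logistic_model.csv"),
                     progress = FALSE)
    # per-predictor univariate ROC (scores = univariate logistic probability)
    for (k in model$selected_predictors) {
      uni <- forward_lr_logistic(feats[, k, drop = FALSE], labels,
                                 entry_p = 1 - 1e-9, removal_p = 1)
      rocs[[k]] <- roc_analysis(uni$fitted, labels)
    }
    if (length(model$selected_predictors) > 0) {
      rocs[["joint_model"]] <- roc_analysis(model$fitted, labels)
    }
    if (length(rocs) > 0) {
      roc_tbl <- purrr::imap_dfr(rocs, function(r, k) {
        dplyr::mutate(tidy(r), predictor = k, .before = 1)
      })
      readr::write_csv(roc_tbl, file.path(output_dir, "roc_curves.csv"),
                       progress = FALSE)
    }
  }

  say("report: writing run report")
  report <- structure(list(
    config = config,
    n_subjects = nrow(clinical),
    group_sizes = as.list(table(clinical$group)),
    n_global_tests = nrow(global_tbl),
    n_nodal_tests = nrow(nodal_tbl),
    global_comparison = global_tbl,
    nodal_comparison = nodal_tbl,
    distribution_tests = dist_tests,
    correlations = correlations,
    model = model,
    model_note = model_note,
    roc = purrr::map(rocs, glance),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fcresponse")),
    output_dir = output_dir
  ), class = "run_report")
  jsonlite::write_json(report_as_list(report),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(output_dir, "report.txt"))
  report
}

# JSON-serializable view of the report (tibbles -> data frames, config echo)
report_as_list <- function(report) {
  cfg <- report$config
  list(
    config = list(
      cohort = unclass(cfg$cohort),
      grid = as.numeric(cfg$grid),
      n_nulls = cfg$n_nulls, n_runs = cfg$n_runs, n_perm = cfg$n_perm,
      alpha = cfg$alpha, entry_p = cfg$entry_p, removal_p = cfg$removal_p,
      degree_sparsity = cfg$degree_sparsity, seed = cfg$seed
    ),
    n_subjects = report$n_subjects,
    group_sizes = report$group_sizes,
    global_comparison = as.data.frame(report$global_comparison),
    nodal_comparison = as.data.frame(report$nodal_comparison),
    distribution_tests = as.data.frame(report$distribution_tests),
    correlations = as.data.frame(report$correlations),
    model = if (!is.null(report$model)) {
      list(selected = report$model$selected_predictors,
           coefficients = as.data.frame(tidy(report$model)),
           trace = as.data.frame(report$model$selection_trace),
           log_likelihood = report$model$log_likelihood)
    },
    model_note = report$model_note,
    roc = purrr::map(report$roc, as.data.frame),
    seed = report$seed,
    package_version = report$package_version
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("== functional connectome treatment-response analysis ==\n")
  cat(sprintf("subjects: %d (%s)\n", x$n_subjects,
              paste(sprintf("%s %s", x$group_sizes, names(x$group_sizes)),
                    collapse = ", ")))
  cat(sprintf("seed: %d | package %s\n\n", x$seed, x$package_version))
  cat(sprintf("global metrics (%d tests; group means +/- SD, permutation p):\n",
              x$n_global_tests))
  g <- x$global_comparison
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-13s %0.4f +/- %0.4f | %0.4f +/- %0.4f  p = %0.4f%s\n",
                g$metric[i], g$mean_a[i], g$sd_a[i], g$mean_b[i], g$sd_b[i],
                g$p[i], if (g$significant[i]) " *" else ""))
  }
  nsig <- sum(x$nodal_comparison$significant)
  cat(sprintf("\nnodal metrics: %d tests, %d significant after FDR\n",
              x$n_nodal_tests, nsig))
  if (nsig > 0) {
    ns <- dplyr::filter(x$nodal_comparison, .data$significant)
    for (i in seq_len(nrow(ns))) {
      cat(sprintf("  %-18s %-8s t = %+0.2f, p = %0.4f, p_fdr = %0.4f\n",
                  ns$metric[i], ns$node[i], ns$statistic[i], ns$p[i], ns$p_fdr[i]))
    }
  }
  if (!is.null(x$model_note)) {
    cat(sprintf("\nlogistic model skipped: %s\n", x$model_note))
  }
  if (!is.null(x$model)) {
    cat(sprintf("\nforward-LR logistic model: %s\n",
                if (length(x$model$selected_predictors) > 0) {
                  paste(x$model$selected_predictors, collapse = ", ")
                } else "(intercept only)"))
    for (nm in names(x$roc)) {
      r <- x$roc[[nm]]
      cat(sprintf("  ROC %-28s AUC = %0.3f (sens %0.3f, spec %0.3f)\n",
                  nm, r$auc, r$sensitivity, r$specificity))
    }
  }
  invisible(x)
}
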