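#' Nonparametric permutation test for a group mean difference
#'
#' Tests the difference in group means by randomly re-partitioning the
#' pooled values into two groups of the original sizes `n_perm` times. The
#' two-tailed p-value uses add-one smoothing,
#' `p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1)`, which avoids p = 0
#' for Monte-Carlo tests; the critical value is the empirical 95th
#' percentile of the absolute null differences (equivalent, under a
#' symmetric null, to 2.5% in each tail of the signed null — the reading
#' under which the nominal two-tailed level is 0.05).
#'
#' @param values_a,values_b Numeric vectors (group A and group B).
#' @param n_perm Number of random re-partitions (default 10000).
#' @param seed Integer seed; the null is deterministic given it.
#' @param metric_name Optional label carried into the result.
#' @return An object of class `perm_test`: list with `metric_name`,
#'   `observed_diff` (mean A - mean B), `null_diffs`, `p_two_tailed`,
#'   `critical_value` and `significant` (`|observed| >=` critical value).
#' @export
#' @examples
#' pt <- permutation_test(rnorm(10, 1), rnorm(10), n_perm = 500, seed = 1)
#' tidy(pt)
permutation_test <- function(values_a, values_b, n_perm = 10000, seed = 1L,
                             metric_name = NULL) {
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a == 0 || n_b == 0) stop("both groups must be nonempty", call. = FALSE)
  stopifnot(n_perm >= 100)
  pool <- c(values_a, values_b)
  n <- n_a + n_b
  observed <- mean(values_a) - mean(values_b)
  total <- sum(pool)
  null_diffs <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n_a)
      s_a <- sum(pool[idx])
      s_a / n_a - (total - s_a) / n_b
    }, numeric(1))
  })
  crit <- unname(quantile(abs(null_diffs), 0.95))
  p <- (1 + sum(abs(null_diffs) >= abs(observed))) / (n_perm + 1)
  structure(list(metric_name = metric_name,
                 observed_diff = observed,
                 null_diffs = null_diffs,
                 p_two_tailed = p,
                 critical_value = crit,
                 significant = abs(observed) >= crit),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test>%s observed diff %.4g, p = %.4g (%d permutations)%s\n",
              if (is.null(x$metric_name)) "" else paste0(" ", x$metric_name, ":"),
              x$observed_diff, x$p_two_tailed, length(x$null_diffs),
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(metric = x$metric_name %||% NA_character_,
                 observed_diff = x$observed_diff,
                 p = x$p_two_tailed,
                 critical_value = x$critical_value,
                 significant = x$significant,
                 n_perm = length(x$null_diffs))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR-adjusted p-values (wraps `stats::p.adjust(method = "BH")`
#' after validating the input range).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.5))
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Permutation comparison of all AUC metrics between groups
#'
#' Runs the permutation test of [permutation_test()] for every metric in a
#' cohort AUC table (one test per global metric and per nodal metric x
#' node), using a shared set of `n_perm` random group re-partitions for
#' efficiency. Nodal p-values are FDR-adjusted within each nodal-metric
#' family; global metrics are reported unadjusted.
#'
#' @param auc_tbl Tibble from [cohort_metrics()] with columns `subject_id`,
#'   `group`, `metric`, `scope`, `node`, `auc`. Every subject must have a
#'   complete set of metrics.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alpha Nominal level used for the `significant` flag of the
#'   FDR-adjusted nodal tests.
#' @return A tibble with one row per test: `scope`, `metric`, `node`,
#'   group means and SDs, `observed_diff` (group A - group B in the factor
#'   level order, i.e. responder - non-responder for simulated cohorts),
#'   `statistic` (observed difference / pooled standard error, a t-like
#'   value for reporting), `critical_value`, `p`, `p_fdr`, `significant`.
#' @export
compare_group_metrics <- function(auc_tbl, n_perm = 10000, seed = 1L,
                                  alpha = 0.05) {
  required <- c("subject_id", "group", "metric", "scope", "node", "auc")
  missing_cols <- setdiff(required, names(auc_tbl))
  if (length(missing_cols) > 0) {
    stop(sprintf("auc_tbl lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  counts <- dplyr::count(auc_tbl, .data$subject_id)
  if (length(unique(counts$n)) > 1) {
    expected <- max(counts$n)
    bad <- counts$subject_id[counts$n != expected]
    stop(sprintf("incomplete metric sets for subject(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  key <- paste(auc_tbl$scope, auc_tbl$metric, auc_tbl$node, sep = "\r")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(auc_tbl, .key = key)[, c("subject_id", "group", ".key", "auc")],
    names_from = ".key", values_from = "auc")
  groups <- wide$group
  lev <- levels(factor(groups))
  is_a <- groups == lev[1]
  n_a <- sum(is_a)
  n_b <- sum(!is_a)
  v <- t(as.matrix(wide[, -(1:2)]))  # tests x subjects

  obs <- rowMeans(v[, is_a, drop = FALSE]) - rowMeans(v[, !is_a, drop = FALSE])
  # shared permutation scheme: one 0/1 assignment matrix for all tests
  perm <- local_seed(seed, {
    p <- matrix(0, ncol(v), n_perm)
    for (b in seq_len(n_perm)) p[sample.int(ncol(v), n_a), b] <- 1
    p
  })
  null_a <- (v %*% perm) / n_a
  null_b <- (v %*% (1 - perm)) / n_b
  null_diffs <- null_a - null_b
  abs_null <- abs(null_diffs)
  p_raw <- (1 + rowSums(abs_null >= abs(obs))) / (n_perm + 1)
  crit <- apply(abs_null, 1L, quantile, probs = 0.95, names = FALSE)

  sd_a <- apply(v[, is_a, drop = FALSE], 1L, sd)
  sd_b <- apply(v[, !is_a, drop = FALSE], 1L, sd)
  pooled_se <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)) *
    sqrt(1 / n_a + 1 / n_b)

  parts <- do.call(rbind, strsplit(rownames(v), "\r", fixed = TRUE))
  res <- tibble::tibble(
    scope = parts[, 1],
    metric = parts[, 2],
    node = ifelse(parts[, 3] == "NA", NA_character_, parts[, 3]),
    group_a = lev[1], group_b = lev[2],
    mean_a = unname(rowMeans(v[, is_a, drop = FALSE])),
    sd_a = unname(sd_a),
    mean_b = unname(rowMeans(v[, !is_a, drop = FALSE])),
    sd_b = unname(sd_b),
    observed_diff = unname(obs),
    statistic = unname(ifelse(pooled_se > 0, obs / pooled_se, 0)),
    critical_value = unname(crit),
    p = unname(p_raw)
  )
  res <- res |>
    dplyr::group_by(.data$scope, .data$metric) |>
    dplyr::mutate(p_fdr = ifelse(.data$scope == "nodal", fdr_adjust(.data$p), NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = ifelse(.data$scope == "nodal",
                                       .data$p_fdr <= alpha,
                                       abs(.data$observed_diff) >= .data$critical_value))
  res
}

#' Two-sample distribution comparison (K-S and Mann-Whitney)
#'
#' Compares two empirical distributions (e.g. pooled degree distributions
#' or link-weight distributions of two groups) with the two-sample
#' Kolmogorov-Smirnov test (supremum of the ECDF difference, asymptotic
#' p-value) and the Mann-Whitney U test (exact enumeration when both
#' samples have at most 20 observations and no ties, normal approximation
#' with continuity and tie correction otherwise).
#'
#' @param sample_a,sample_b Numeric vectors with at least 2 values each.
#' @return A one-row tibble: `ks_statistic`, `ks_p`, `mwu_statistic`
#'   (U for the first sample), `mwu_p`.
#' @export
#' @examples
#' compare_distributions(rnorm(30), rnorm(30, 1))
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  use_exact <- length(sample_a) <= 20 && length(sample_b) <= 20
  mwu <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(ks_statistic = unname(ks$statistic),
                 ks_p = ks$p.value,
                 mwu_statistic = unname(mwu$statistic),
                 mwu_p = mwu$p.value)
}
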