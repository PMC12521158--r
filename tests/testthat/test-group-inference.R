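test_that("permutation p-values match exhaustive enumeration on small pools", {
  # fully separated groups: only the 2 extreme partitions of C(6,3) = 20
  # reach |diff| = 10, so the exact p is 0.1
  a <- c(10, 10, 10); b <- c(0, 0, 0)
  expect_equal(exact_perm_p(a, b), 0.1)
  pt <- permutation_test(a, b, n_perm = 20000, seed = 1)
  expect_lt(abs(pt$p_two_tailed - 0.1), 0.01)

  set.seed(41)
  for (i in 1:4) {
    a <- rnorm(4); b <- rnorm(5, mean = runif(1, 0, 2))
    p_exact <- exact_perm_p(a, b)
    pt <- permutation_test(a, b, n_perm = 8000, seed = i)
    expect_lt(abs(pt$p_two_tailed - p_exact), 0.03)
  }
})

test_that("permutation test handles constants, determinism and the significance flag", {
  pt <- permutation_test(rep(2, 5), rep(2, 7), n_perm = 200, seed = 1)
  expect_equal(pt$observed_diff, 0)
  expect_equal(pt$p_two_tailed, 1)

  same_a <- c(1.2, 0.3, -0.5, 2, 0.7)
  same_b <- c(0.1, -1, 0.4, 0.2, -0.3)
  q1 <- permutation_test(same_a, same_b, n_perm = 1000, seed = 5)
  q2 <- permutation_test(same_a, same_b, n_perm = 1000, seed = 5)
  expect_identical(q1$null_diffs, q2$null_diffs)

  # significant flag agrees with p <= 0.05 up to null discreteness
  set.seed(42)
  for (i in 1:20) {
    shift <- runif(1, 0, 1.5)
    pt <- permutation_test(rnorm(15, shift), rnorm(15), n_perm = 2000, seed = i)
    if (abs(pt$p_two_tailed - 0.05) > 2 / 2001) {
      expect_equal(pt$significant, pt$p_two_tailed <= 0.05)
    }
  }
  expect_error(permutation_test(numeric(0), rnorm(3), n_perm = 100), "nonempty")
})

test_that("Benjamini-Hochberg adjustment matches the hand-worked example", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("distribution comparison reproduces exact K-S and U statistics", {
  same <- c(1, 2, 3, 4)
  res <- compare_distributions(same, same)
  expect_equal(res$ks_statistic, 0)

  res <- compare_distributions(c(1, 2, 3), c(11, 12, 13))
  expect_equal(res$ks_statistic, 1)

  # brute-force U over all 4 pairs: only (2 > 1.5) counts
  res <- compare_distributions(c(1, 2), c(1.5, 2.5))
  expect_equal(unname(res$mwu_statistic), 1)
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
})

test_that("cohort-level comparison table is complete and detects a planted shift", {
  set.seed(43)
  n_a <- 12; n_b <- 10
  ids <- sprintf("s%02d", 1:(n_a + n_b))
  group <- factor(rep(c("responder", "nonresponder"), c(n_a, n_b)),
                  levels = c("responder", "nonresponder"))
  make_rows <- function(metric, scope, node, values) {
    tibble::tibble(subject_id = ids, group = group, metric = metric,
                   scope = scope, node = node, auc = values)
  }
  tbl <- dplyr::bind_rows(
    make_rows("Eglob", "global", NA_character_, rnorm(22)),
    make_rows("modularity", "global", NA_character_,
              c(rnorm(n_a, 0), rnorm(n_b, 3))),          # strong planted effect
    make_rows("degree", "nodal", "A", rnorm(22)),
    make_rows("degree", "nodal", "B", rnorm(22)),
    make_rows("degree", "nodal", "C", c(rnorm(n_a), rnorm(n_b, 4))))
  res <- compare_group_metrics(tbl, n_perm = 2000, seed = 9)
  expect_equal(nrow(res), 5)
  expect_equal(sum(res$scope == "global"), 2)
  expect_true(all(is.na(res$p_fdr[res$scope == "global"])))
  expect_true(all(!is.na(res$p_fdr[res$scope == "nodal"])))

  mod <- res[res$metric == "modularity", ]
  expect_lt(mod$p, 0.01)
  expect_true(mod$significant)
  expect_lt(mod$observed_diff, 0)  # responder mean - nonresponder mean
  nodal_c <- res[res$scope == "nodal" & res$node == "C", ]
  expect_true(nodal_c$significant)
  expect_gte(nodal_c$p_fdr, nodal_c$p)

  # group means reported as in the data
  eg <- res[res$metric == "Eglob", ]
  vals <- tbl$auc[tbl$metric == "Eglob"]
  expect_equal(eg$mean_a, mean(vals[group == "responder"]))
  expect_equal(eg$sd_b, sd(vals[group == "nonresponder"]))

  # incomplete subject -> error naming it
  expect_error(compare_group_metrics(tbl[-1, ], n_perm = 200, seed = 1), "s01")
})

test_that("shared-permutation comparison agrees with the single test", {
  set.seed(44)
  ids <- sprintf("s%02d", 1:20)
  group <- factor(rep(c("responder", "nonresponder"), each = 10),
                  levels = c("responder", "nonresponder"))
  vals <- c(rnorm(10, 0.8), rnorm(10))
  tbl <- tibble::tibble(subject_id = ids, group = group, metric = "Cp",
                        scope = "global", node = NA_character_, auc = vals)
  res <- compare_group_metrics(tbl, n_perm = 5000, seed = 2)
  single <- permutation_test(vals[1:10], vals[11:20], n_perm = 5000, seed = 3)
  expect_equal(res$observed_diff, single$observed_diff)
  expect_equal(res$p, single$p_two_tailed, tolerance = 0.03)
})
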