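test_that("block covariance matrix is constructed exactly", {
  s <- cohort_spec(n_rois = 4, n_modules = 2,
                   within_module_r = 0.6, between_module_r = 0.1,
                   seed = 1)
  m <- make_group_covariance(s, "responder")
  expected <- rbind(c(1, .6, .1, .1),
                    c(.6, 1, .1, .1),
                    c(.1, .1, 1, .6),
                    c(.1, .1, .6, 1))
  expect_equal(unname(m), expected)

  s0 <- cohort_spec(n_rois = 5, n_modules = 2,
                    within_module_r = 0, between_module_r = 0, seed = 1)
  expect_equal(unname(make_group_covariance(s0, "nonresponder")), diag(5))
})

test_that("default 90-ROI model correlation matrices are positive semi-definite", {
  s <- cohort_spec()
  for (g in c("responder", "nonresponder")) {
    m <- make_group_covariance(s, g)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(diag(m), setNames(rep(1, 90), rownames(m)))
  }
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(cohort_spec(within_module_r = 0.2, between_module_r = 0.3),
               "between_module_r")
  expect_error(cohort_spec(responder_reduction_range = c(0.4, 0.9)),
               "straddle")
  expect_error(cohort_spec(nonresponder_reduction_range = c(1, 1)),
               "straddle")
})

test_that("subject time series are deterministic and carry the model correlation", {
  cv <- diag(6)
  a <- simulate_subject_timeseries(cv, 100, noise_sd = 0.3, seed = 11)
  b <- simulate_subject_timeseries(cv, 100, noise_sd = 0.3, seed = 11)
  expect_identical(a, b)

  # identity model: empirical cross-correlations near zero at large T
  big <- simulate_subject_timeseries(diag(5), 20000, seed = 2)
  r <- cor(big)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # block model: within-block empirical r recovers the generating value
  s <- cohort_spec(n_rois = 10, n_modules = 2,
                   within_module_r = 0.6, between_module_r = 0.0, seed = 1)
  m <- make_group_covariance(s, "responder")
  x <- simulate_subject_timeseries(m, 2000, noise_sd = 0, seed = 3)
  r <- cor(x)
  blocks <- rep(1:2, each = 5)
  within <- r[outer(blocks, blocks, `==`) & upper.tri(r)]
  expect_lt(abs(mean(within) - 0.6), 0.05)

  expect_error(simulate_subject_timeseries(diag(10), 11, seed = 1),
               "n_rois \\+ 2")
})

test_that("simulated cohorts have consistent labels and reproducible tables", {
  coh <- simulate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(coh$clinical), 69)
  expect_equal(sum(coh$clinical$responder), 37)
  expect_equal(sum(!coh$clinical$responder), 32)
  # the >= 50% reduction rule reproduces the generating assignment exactly
  derived <- ifelse(coh$clinical$reduction_rate >= 0.5, "responder", "nonresponder")
  expect_identical(derived, as.character(coh$clinical$group))
  expect_true(all(coh$clinical$hamd17_pre >= 8))
  expect_equal(length(coh$time_series), 69)
  expect_equal(dim(coh$time_series[[1]]), c(230, 90))
  expect_false(any(duplicated(coh$clinical$subject_id)))

  coh2 <- simulate_cohort(cohort_spec(seed = 1))
  expect_identical(coh$clinical, coh2$clinical)
  expect_identical(coh$time_series[[5]], coh2$time_series[[5]])

  coh3 <- simulate_cohort(cohort_spec(seed = 2))
  expect_false(identical(coh$clinical$hamd17_pre, coh3$clinical$hamd17_pre))
})

test_that("degenerate reduction range [0,0] leaves scores unchanged", {
  spec <- cohort_spec(n_responders = 4, n_nonresponders = 6, n_rois = 10,
                      n_timepoints = 30, n_modules = 2,
                      nonresponder_reduction_range = c(0, 0), seed = 5)
  coh <- simulate_cohort(spec)
  nr <- dplyr::filter(coh$clinical, group == "nonresponder")
  expect_equal(nr$hamd17_post, nr$hamd17_pre)
})
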