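test_that("responder labelling follows the 50% reduction boundary", {
  tbl <- label_responders(tibble::tibble(
    hamd17_pre = c(20, 20, 18, 16),
    hamd17_post = c(10, 11, 18, 20)))
  expect_equal(tbl$reduction_rate, c(0.5, 0.45, 0, -0.25))
  expect_equal(tbl$responder, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.character(tbl$group),
               c("responder", rep("nonresponder", 3)))
  expect_error(label_responders(tibble::tibble(hamd17_pre = 0, hamd17_post = 0)),
               "positive")
})

test_that("partial correlation reduces to Pearson and matches the closed form", {
  set.seed(51)
  x <- rnorm(30); y <- x + rnorm(30)
  pc <- partial_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$r_partial, unname(ct$estimate))
  expect_equal(pc$p, ct$p.value)
  expect_equal(pc$df, 28)

  # one-covariate fixture checked against the 3x3 correlation-matrix identity
  x6 <- c(1.2, 0.5, -0.3, 2.1, 0.8, -1.0)
  y6 <- c(0.9, 1.1, -0.2, 1.8, 0.2, -0.7)
  z6 <- c(0.3, -0.5, 1.2, 0.8, -1.1, 0.4)
  pc <- partial_correlation(x6, y6, cbind(z = z6))
  rxy <- cor(x6, y6); rxz <- cor(x6, z6); ryz <- cor(y6, z6)
  r_formula <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r_partial, r_formula, tolerance = 1e-12)
  expect_equal(pc$df, 3)

  # outcome fully explained by the covariates: residual correlation 0
  y_lin <- 2 + 3 * z6
  expect_equal(partial_correlation(x6, y_lin, cbind(z6))$r_partial, 0)

  expect_error(partial_correlation(x6, y6, cbind(z6, 2 * z6)), "rank")
  expect_error(partial_correlation(x6[1:4], y6[1:4], cbind(z6[1:4])), "n >")
})

test_that("forward-LR selection enters real predictors and skips noise", {
  # balanced 2x2 with no association: LR chi-square is 0, nothing enters
  fit <- forward_lr_logistic(cbind(f = c(1, 0, 1, 0, 1, 0, 1, 0)),
                             c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_length(fit$selected_predictors, 0)
  expect_equal(nrow(fit$selection_trace), 0)

  # planted 2-SD group shift among noise features (single seed; the
  # repeated-seed selection rate is exercised in the acceptance suite)
  set.seed(52)
  n <- 69
  y <- rep(c(TRUE, FALSE), c(37, 32))
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[y, 1] <- x[y, 1] + 2
  fit <- forward_lr_logistic(x, y)
  expect_true("f1" %in% fit$selected_predictors)
  expect_equal(fit$selection_trace$variable[1], "f1")
  expect_equal(fit$selection_trace$action[1], "enter")

  # Wald odds-ratio columns are internally consistent
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_equal(cf$odds_ratio, exp(cf$estimate))
  expect_true(all(cf$or_ci_low < cf$odds_ratio & cf$odds_ratio < cf$or_ci_high))

  # log-likelihood gradient vanishes at convergence
  sel <- fit$selected_predictors
  xx <- cbind(1, x[, sel, drop = FALSE])
  eta <- as.numeric(xx %*% coef(fit$fit))
  grad <- t(xx) %*% (y - stats::plogis(eta))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("perfect separation is detected and named", {
  y <- rep(c(TRUE, FALSE), each = 10)
  x <- cbind(sep = c(rnorm(10, 10), rnorm(10, -10)), noise = rnorm(20))
  expect_error(forward_lr_logistic(x, y), "separation.*sep")
  expect_error(forward_lr_logistic(cbind(a = rnorm(4)), c(TRUE, TRUE, TRUE, FALSE)),
               "per class")
})

test_that("ROC analysis matches pair counting, conventions and label flips", {
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)

  sep <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$operating_point$sensitivity, 1)
  expect_equal(sep$operating_point$specificity, 1)

  flat <- roc_analysis(rep(0.5, 8), rep(c(0, 1), 4))
  expect_equal(flat$auc, 0.5)

  # Mann-Whitney identity and label-flip antisymmetry on tie-free data
  set.seed(53)
  for (i in 1:5) {
    scores <- sample(seq(0.01, 1, by = 0.01), 24)
    labels <- rep(c(TRUE, FALSE), 12)
    r <- roc_analysis(scores, labels)
    u <- sum(outer(scores[labels], scores[!labels], `>`))
    expect_equal(r$auc, u / (12 * 12), tolerance = 1e-12)
    r_flip <- roc_analysis(scores, !labels)
    expect_equal(r_flip$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_error(roc_analysis(rnorm(4), rep(TRUE, 4)), "both classes")
})

test_that("ROC AUC agrees with the pROC reference implementation", {
  set.seed(54)
  for (i in 1:5) {
    labels <- rep(c(TRUE, FALSE), c(15, 12))
    scores <- rnorm(27) + labels * runif(1, 0, 2)
    r <- roc_analysis(scores, labels)
    ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                               direction = "<", levels = c(FALSE, TRUE),
                               quiet = TRUE))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
  }
})
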