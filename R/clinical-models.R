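#' Label treatment responders from HAMD-17 reduction
#'
#' Derives the reduction rate `(pre - post) / pre` of the 17-item Hamilton
#' Depression Rating Scale and the responder label (reduction >= 50%; the
#' boundary case counts as a responder). A post-treatment score above the
#' pre-treatment score yields a negative reduction rate and a non-responder
#' label.
#'
#' @param table Data frame with integer columns `hamd17_pre` and
#'   `hamd17_post`; `hamd17_pre` must be positive for every row.
#' @return The input as a tibble with `reduction_rate` and `responder`
#'   columns added (and a `group` factor column if not already present).
#' @export
#' @examples
#' label_responders(tibble::tibble(hamd17_pre = c(20, 20, 18),
#'                                 hamd17_post = c(10, 11, 18)))
label_responders <- function(table) {
  tbl <- tibble::as_tibble(table)
  stopifnot(all(c("hamd17_pre", "hamd17_post") %in% names(tbl)))
  if (any(tbl$hamd17_pre <= 0)) {
    stop("hamd17_pre must be positive (reduction rate undefined at 0)",
         call. = FALSE)
  }
  tbl <- dplyr::mutate(
    tbl,
    reduction_rate = (.data$hamd17_pre - .data$hamd17_post) / .data$hamd17_pre,
    responder = .data$reduction_rate >= 0.5
  )
  if (!"group" %in% names(tbl)) {
    tbl$group <- factor(ifelse(tbl$responder, "responder", "nonresponder"),
                        levels = c("responder", "nonresponder"))
  }
  tbl
}

#' Partial correlation controlling for covariates
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' covariates (with intercept) from both by least squares; the p-value is
#' the two-tailed t-test of the residual correlation with
#' `df = n - 2 - n_covariates`. With no covariates this reduces exactly to
#' the Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data frame of covariates
#'   (e.g. age and sex); must be full rank together with the intercept.
#' @return One-row tibble: `r_partial`, `df`, `statistic`, `p`, `n`,
#'   `covariates`.
#' @export
#' @examples
#' z <- rnorm(30)
#' partial_correlation(z + rnorm(30), z + rnorm(30), covariates = cbind(z))
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    z <- matrix(numeric(0), n, 0)
  } else {
    z <- as.matrix(covariates)
    storage.mode(z) <- "double"
    stopifnot(nrow(z) == n)
  }
  k <- ncol(z)
  if (n <= k + 3) {
    stop(sprintf("need n > n_covariates + 3 (n = %d, covariates = %d)", n, k),
         call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, z)
  if (qr(design)$rank < ncol(design)) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  rx <- lm.fit(design, x)$residuals
  ry <- lm.fit(design, y)$residuals
  degenerate <- function(res, orig) {
    sd(res) <= 1e-10 * max(sd(orig), .Machine$double.eps)
  }
  if (degenerate(rx, x) || degenerate(ry, y)) {
    # a variable fully explained by the covariates: residual correlation 0
    r <- 0
  } else {
    r <- cor(rx, ry)
  }
  df <- n - 2L - k
  stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(stat), df)
  tibble::tibble(r_partial = r, df = df, statistic = stat, p = p, n = n,
                 covariates = paste(colnames(z) %||% character(0), collapse = ","))
}

# fit a logistic model by IRLS (stats::glm), flagging perfect separation
fit_logistic <- function(df, vars) {
  fml <- if (length(vars) == 0) {
    y ~ 1
  } else {
    stats::reformulate(sprintf("`%s`", vars), response = "y")
  }
  fit <- suppressWarnings(
    glm(fml, data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100))
  )
  fitted <- fit$fitted.values
  if (length(vars) > 0 &&
      min(fitted[df$y == 1]) > 1 - 1e-6 && max(fitted[df$y == 0]) < 1e-6) {
    cf <- coef(fit)[-1]
    scale <- vapply(vars, function(v) sd(df[[v]]), numeric(1))
    worst <- vars[which.max(abs(cf) * scale)]
    stop(sprintf("perfect separation detected (feature %s)", worst),
         call. = FALSE)
  }
  fit
}

#' Forward likelihood-ratio stepwise logistic regression
#'
#' Builds a binary logistic model by forward selection with
#' likelihood-ratio entry tests: at each step the candidate whose LR
#' chi-square (twice the log-likelihood gain over the current model, 1 df)
#' has the smallest p-value below `entry_p` enters; after each entry, any
#' included variable whose removal LR p-value exceeds `removal_p` is
#' dropped. Selection stops when no candidate qualifies. Fits use
#' iteratively reweighted least squares (convergence tolerance 1e-8,
#' at most 100 iterations); confidence intervals for odds ratios are Wald
#' intervals.
#'
#' @param features Numeric matrix or data frame of candidate predictors
#'   (columns named). Typically the metrics found significant in the group
#'   comparison; the candidate pool is passed in explicitly to keep the
#'   inferential chain visible.
#' @param labels Logical (or 0/1, or two-level factor) outcome, `TRUE` for
#'   the positive class (responder); at least 2 subjects per class.
#' @param entry_p,removal_p Entry and removal thresholds (defaults 0.05 and
#'   0.10, the conventional stepwise defaults).
#' @param standardize Scale features to unit variance before fitting
#'   (odds ratios are then per SD).
#' @return An object of class `forward_lr_fit`: `selected_predictors`,
#'   `coefficients` (tibble with estimates, Wald statistics, odds ratios
#'   and 95% CIs), `log_likelihood`, `selection_trace` (per-step LR tests),
#'   `fitted` probabilities and the underlying `glm` fit.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- runif(50) < stats::plogis(2 * x[, 1])
#' fit <- forward_lr_logistic(x, y)
#' fit$selected_predictors
forward_lr_logistic <- function(features, labels, entry_p = 0.05,
                                removal_p = 0.10, standardize = FALSE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  y <- as.integer(as.logical(labels))
  stopifnot(length(y) == nrow(x))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  if (standardize) x <- scale(x)
  df <- data.frame(y = y, x, check.names = FALSE)
  candidates <- colnames(x)

  selected <- character(0)
  trace <- list()
  step <- 0L
  current <- fit_logistic(df, selected)
  seen_sets <- character(0)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    entry <- dplyr::bind_rows(lapply(remaining, function(v) {
      fit <- fit_logistic(df, c(selected, v))
      chi <- current$deviance - fit$deviance
      tibble::tibble(variable = v, lr_chisq = chi, df = 1L,
                     p = pchisq(chi, df = 1L, lower.tail = FALSE))
    }))
    best <- entry[which.min(entry$p), ]
    if (best$p >= entry_p) break
    step <- step + 1L
    selected <- c(selected, best$variable)
    current <- fit_logistic(df, selected)
    trace[[length(trace) + 1L]] <-
      dplyr::mutate(best, step = step, action = "enter")
    # backward pass on LR removal tests
    repeat {
      if (length(selected) == 0) break
      removal <- dplyr::bind_rows(lapply(selected, function(v) {
        fit <- fit_logistic(df, setdiff(selected, v))
        chi <- fit$deviance - current$deviance
        tibble::tibble(variable = v, lr_chisq = chi, df = 1L,
                       p = pchisq(chi, df = 1L, lower.tail = FALSE))
      }))
      worst <- removal[which.max(removal$p), ]
      if (worst$p <= removal_p) break
      step <- step + 1L
      selected <- setdiff(selected, worst$variable)
      current <- fit_logistic(df, selected)
      trace[[length(trace) + 1L]] <-
        dplyr::mutate(worst, step = step, action = "remove")
      sig <- paste(sort(selected), collapse = "|")
      if (sig %in% seen_sets) break  # guard against entry/removal cycling
      seen_sets <- c(seen_sets, sig)
    }
  }

  est <- coef(current)
  se <- sqrt(diag(stats::vcov(current)))
  zval <- est / se
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(zval),
    p = unname(2 * pnorm(-abs(zval))),
    odds_ratio = exp(unname(est)),
    or_ci_low = exp(unname(est - 1.959964 * se)),
    or_ci_high = exp(unname(est + 1.959964 * se))
  )
  structure(list(
    selected_predictors = selected,
    coefficients = coefs,
    log_likelihood = as.numeric(logLik(current)),
    deviance = current$deviance,
    null_deviance = current$null.deviance,
    selection_trace = if (length(trace) > 0) {
      dplyr::bind_rows(trace)[, c("step", "action", "variable", "lr_chisq", "df", "p")]
    } else {
      tibble::tibble(step = integer(0), action = character(0),
                     variable = character(0), lr_chisq = numeric(0),
                     df = integer(0), p = numeric(0))
    },
    fitted = unname(current$fitted.values),
    entry_p = entry_p,
    removal_p = removal_p,
    n = length(y),
    fit = current
  ), class = "forward_lr_fit")
}

#' @export
print.forward_lr_fit <- function(x, ...) {
  cat(sprintf("<forward_lr_fit> %d predictor(s) selected\n",
              length(x$selected_predictors)))
  if (length(x$selected_predictors) > 0) {
    cat("  selected:", paste(x$selected_predictors, collapse = ", "), "\n")
  }
  cat(sprintf("  log-likelihood %.3f\n", x$log_likelihood))
  invisible(x)
}

#' @rdname forward_lr_logistic
#' @param x A `forward_lr_fit`.
#' @param ... Unused.
#' @export
tidy.forward_lr_fit <- function(x, ...) x$coefficients

#' @rdname forward_lr_logistic
#' @export
glance.forward_lr_fit <- function(x, ...) {
  tibble::tibble(n = x$n,
                 n_selected = length(x$selected_predictors),
                 log_likelihood = x$log_likelihood,
                 deviance = x$deviance,
                 null_deviance = x$null_deviance,
                 n_steps = nrow(x$selection_trace))
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Sweeps every distinct score value as a classification threshold
#' (predict positive when `score >= threshold`), computes sensitivity and
#' specificity at each, integrates the curve by the trapezoidal rule over
#' (1 - specificity, sensitivity), and reports the operating point
#' maximizing Youden's J = sensitivity + specificity - 1 (ties broken
#' toward higher specificity). When all scores are identical the curve is
#' a single degenerate point and the AUC is 0.5 by convention.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical / 0-1 outcome; both classes must be present.
#' @return An object of class `roc_curve`: `curve` tibble (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, and `operating_point` (list with
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`).
#' @export
#' @examples
#' r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' glance(r)
roc_analysis <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    curve <- tibble::tibble(threshold = scores[1],
                            sensitivity = 1, specificity = 0)
    op <- list(threshold = scores[1], sensitivity = 0, specificity = 1,
               youden_j = 0)
    return(structure(list(curve = curve, auc = 0.5, operating_point = op,
                          n_pos = n_pos, n_neg = n_neg),
                     class = "roc_curve"))
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(y & scores >= t) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(!y & scores < t) / n_neg, numeric(1))
  curve <- tibble::tibble(threshold = thr, sensitivity = sens,
                          specificity = spec)
  fpr <- 1 - spec
  auc <- trapz(fpr, sens)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  op <- list(threshold = thr[best], sensitivity = sens[best],
             specificity = spec[best], youden_j = j[best])
  structure(list(curve = curve, auc = auc, operating_point = op,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden point: sensitivity %.3f, specificity %.3f\n",
              x$operating_point$sensitivity, x$operating_point$specificity))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' @rdname roc_analysis
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc,
                 sensitivity = x$operating_point$sensitivity,
                 specificity = x$operating_point$specificity,
                 youden_j = x$operating_point$youden_j,
                 threshold = x$operating_point$threshold,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
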