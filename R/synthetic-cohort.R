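#' Specify a synthetic two-group cohort
#'
#' Defines the generative model for a synthetic treatment-response cohort:
#' two groups of subjects ("responder" / "nonresponder") whose regional BOLD
#' time series are drawn from modular (block-structured) multivariate-normal
#' models, plus a clinical table with Hamilton depression (HAMD-17) and
#' anxiety (HAMA) scores. A modular correlation structure is used because
#' block density directly manipulates network segregation — clustering,
#' local efficiency and modularity — which is the group effect of interest
#' in treatment-response connectomics.
#'
#' The default group parameters plant a mild segregation increase in the
#' non-responder group (denser within-module, sparser between-module
#' correlation), so that non-responders show higher normalized clustering,
#' local efficiency, modularity and small-worldness. The default clinical
#' marginals emulate an adolescent depression cohort: pre-treatment HAMD-17
#' around 18.4 +/- 5.5 (truncated at the >= 8 inclusion threshold), with
#' responders reducing their score by 55-100% and non-responders by -20-35%.
#'
#' @param n_responders,n_nonresponders Group sizes (defaults 37 and 32).
#' @param n_rois Number of network nodes (default 90, AAL parcellation).
#' @param n_timepoints Retained BOLD volumes per subject (default 230).
#' @param n_modules Number of equally sized correlation blocks (default 6).
#' @param within_module_r,between_module_r Named numeric vectors with
#'   elements `responder` and `nonresponder`: the model correlation inside
#'   and between blocks for each group. Must satisfy
#'   `0 <= between < within < 1` per group.
#' @param subject_noise_sd Standard deviation of independent per-channel
#'   measurement noise added on top of the unit-variance latent signal.
#' @param hamd_pre_mean,hamd_pre_sd Pre-treatment HAMD-17 distribution
#'   (normal, truncated at >= 8, rounded to integer).
#' @param hama_pre_mean,hama_pre_sd Pre-treatment HAMA distribution
#'   (normal, truncated at >= 1, rounded to integer).
#' @param responder_reduction_range,nonresponder_reduction_range Intervals
#'   of the HAMD-17 reduction proportion `u` per group; post-treatment score
#'   is `round(pre * (1 - u))`. The responder range must lie entirely at or
#'   above 0.50 and the non-responder range entirely below it, so generated
#'   labels agree with the >= 50% reduction rule.
#' @param confound_age_sex If `TRUE`, age and sex distributions differ
#'   between groups (for exercising covariate adjustment); by default they
#'   are group-independent.
#' @param seed Master seed; every random draw in [simulate_cohort()] derives
#'   from it.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [make_group_covariance()]
#' @export
#' @examples
#' spec <- cohort_spec(n_responders = 5, n_nonresponders = 5, n_rois = 20,
#'                     n_timepoints = 60, seed = 1)
#' spec
cohort_spec <- function(n_responders = 37,
                        n_nonresponders = 32,
                        n_rois = 90,
                        n_timepoints = 230,
                        n_modules = 6,
                        within_module_r = c(responder = 0.300, nonresponder = 0.310),
                        between_module_r = c(responder = 0.100, nonresponder = 0.097),
                        subject_noise_sd = 0.6,
                        hamd_pre_mean = 18.4,
                        hamd_pre_sd = 5.5,
                        hama_pre_mean = 15.4,
                        hama_pre_sd = 6.7,
                        responder_reduction_range = c(0.55, 1.00),
                        nonresponder_reduction_range = c(-0.20, 0.35),
                        confound_age_sex = FALSE,
                        seed = 1L) {
  groups <- c("responder", "nonresponder")
  norm_group_par <- function(x, what) {
    if (length(x) == 1L) x <- c(responder = unname(x), nonresponder = unname(x))
    if (!all(groups %in% names(x))) {
      stop(sprintf("`%s` must be named with elements 'responder' and 'nonresponder'", what),
           call. = FALSE)
    }
    x[groups]
  }
  within_module_r <- norm_group_par(within_module_r, "within_module_r")
  between_module_r <- norm_group_par(between_module_r, "between_module_r")

  spec <- structure(list(
    n_responders = as.integer(n_responders),
    n_nonresponders = as.integer(n_nonresponders),
    n_rois = as.integer(n_rois),
    n_timepoints = as.integer(n_timepoints),
    n_modules = as.integer(n_modules),
    within_module_r = within_module_r,
    between_module_r = between_module_r,
    subject_noise_sd = subject_noise_sd,
    hamd_pre_mean = hamd_pre_mean,
    hamd_pre_sd = hamd_pre_sd,
    hama_pre_mean = hama_pre_mean,
    hama_pre_sd = hama_pre_sd,
    responder_reduction_range = as.numeric(responder_reduction_range),
    nonresponder_reduction_range = as.numeric(nonresponder_reduction_range),
    confound_age_sex = isTRUE(confound_age_sex),
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_responders >= 1L, spec$n_nonresponders >= 1L,
            spec$n_rois >= 2L, spec$n_modules >= 1L,
            spec$n_modules <= spec$n_rois,
            spec$subject_noise_sd >= 0)
  for (g in c("responder", "nonresponder")) {
    w <- spec$within_module_r[[g]]
    b <- spec$between_module_r[[g]]
    if (!(w >= 0 && w < 1)) {
      stop(sprintf("within_module_r[%s] = %g must lie in [0, 1)", g, w), call. = FALSE)
    }
    if (!(b >= 0 && b <= w)) {
      stop(sprintf("between_module_r[%s] = %g must lie in [0, within_module_r]", g, b),
           call. = FALSE)
    }
  }
  rr <- spec$responder_reduction_range
  nr <- spec$nonresponder_reduction_range
  if (length(rr) != 2L || length(nr) != 2L || rr[1] > rr[2] || nr[1] > nr[2]) {
    stop("reduction ranges must be intervals c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (rr[1] < 0.5 || nr[2] >= 0.5) {
    stop(paste0("reduction ranges straddle the 0.50 responder boundary ",
                "(responder range must lie in [0.50, 1], non-responder range below 0.50); ",
                "generated labels would contradict the generating groups"), call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  subjects: %d responders + %d non-responders\n",
              x$n_responders, x$n_nonresponders))
  cat(sprintf("  network:  %d ROIs, %d timepoints, %d modules\n",
              x$n_rois, x$n_timepoints, x$n_modules))
  cat(sprintf("  block r:  responder %0.3f/%0.3f, non-responder %0.3f/%0.3f (within/between)\n",
              x$within_module_r[["responder"]], x$between_module_r[["responder"]],
              x$within_module_r[["nonresponder"]], x$between_module_r[["nonresponder"]]))
  cat(sprintf("  noise sd: %0.3g, seed: %d\n", x$subject_noise_sd, x$seed))
  invisible(x)
}

# modules are contiguous, as equal as possible (exactly equal when
# n_rois %% n_modules == 0, the default 90/6)
module_assignment <- function(n_rois, n_modules) {
  sizes <- rep(n_rois %/% n_modules, n_modules)
  extra <- n_rois %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_modules), times = sizes)
}

#' Model correlation matrix of one cohort group
#'
#' Builds the block-structured model correlation matrix for one group of a
#' [cohort_spec()]: unit diagonal, `within_module_r` inside each of
#' `n_modules` contiguous equal blocks, `between_module_r` elsewhere. If the
#' construction is not positive semi-definite it is repaired by clipping
#' negative eigenvalues at zero and rescaling to unit diagonal.
#'
#' @param spec A [cohort_spec()].
#' @param group `"responder"` or `"nonresponder"`.
#' @return An `n_rois` x `n_rois` correlation matrix with ROI labels as
#'   dimnames.
#' @export
#' @examples
#' s <- cohort_spec(n_rois = 4, n_modules = 2,
#'                  within_module_r = 0.6, between_module_r = 0.1,
#'                  responder_reduction_range = c(0.5, 1),
#'                  nonresponder_reduction_range = c(0, 0.4))
#' make_group_covariance(s, "responder")
make_group_covariance <- function(spec, group = c("responder", "nonresponder")) {
  group <- match.arg(group)
  validate_cohort_spec(spec)
  n <- spec$n_rois
  w <- spec$within_module_r[[group]]
  b <- spec$between_module_r[[group]]
  mod <- module_assignment(n, spec$n_modules)
  m <- matrix(b, n, n)
  same <- outer(mod, mod, `==`)
  m[same] <- w
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(sprintf(paste0("group covariance not positive semi-definite after repair ",
                          "(within_module_r = %g, between_module_r = %g, n_modules = %d)"),
                   w, b, spec$n_modules), call. = FALSE)
    }
  }
  m <- (m + t(m)) / 2
  labels <- default_roi_labels(n)
  dimnames(m) <- list(labels, labels)
  m
}

#' Simulate one subject's regional BOLD time series
#'
#' Draws `n_timepoints` independent samples from a zero-mean multivariate
#' normal with the given model correlation and adds independent Gaussian
#' measurement noise of standard deviation `noise_sd` to every channel.
#' This stands in for preprocessed (nuisance-regressed, filtered) regional
#' BOLD signal; it makes no attempt to model autocorrelation, head motion
#' or physiological noise.
#'
#' @param cov Positive semi-definite model correlation/covariance matrix
#'   (ROI labels taken from its dimnames when present).
#' @param n_timepoints Number of samples (must be at least `nrow(cov) + 2`
#'   so that downstream correlation estimation is well posed).
#' @param noise_sd Nonnegative noise standard deviation.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param subject_id Optional subject identifier stored as an attribute.
#' @return A `n_timepoints` x `n_rois` numeric matrix with ROI-label
#'   column names and attribute `subject_id`.
#' @export
#' @examples
#' ts <- simulate_subject_timeseries(diag(4), n_timepoints = 50, seed = 1)
#' dim(ts)
simulate_subject_timeseries <- function(cov, n_timepoints, noise_sd = 0,
                                        seed = NULL, subject_id = NULL) {
  n <- nrow(cov)
  stopifnot(is.matrix(cov), ncol(cov) == n, noise_sd >= 0)
  if (n_timepoints < n + 2L) {
    stop(sprintf(paste0("n_timepoints = %d is too short for %d ROIs ",
                        "(need at least n_rois + 2 = %d for downstream ",
                        "correlation estimation)"),
                 n_timepoints, n, n + 2L), call. = FALSE)
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("`cov` is not positive semi-definite", call. = FALSE)
  }
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  x <- local_seed(seed, {
    z <- matrix(rnorm(n_timepoints * n), n_timepoints, n) %*% root
    if (noise_sd > 0) {
      z <- z + matrix(rnorm(n_timepoints * n, sd = noise_sd), n_timepoints, n)
    }
    z
  })
  labels <- colnames(cov) %||% default_roi_labels(n)
  colnames(x) <- labels
  attr(x, "subject_id") <- subject_id
  x
}

#' Simulate a complete two-group cohort
#'
#' Generates per-subject ROI time series from each subject's group model
#' correlation matrix ([make_group_covariance()]) and a clinical table with
#' age (uniform over 13-18 years), sex (Bernoulli 1/2), pre-treatment
#' HAMD-17 and HAMA scores, and post-treatment scores derived by drawing a
#' reduction proportion from the group's reduction range. Responder labels
#' derived from the >= 50% HAMD-17 reduction rule are guaranteed to equal
#' the generating group assignment: after integer rounding the
#' post-treatment score is clamped to the correct side of the boundary (the
#' clamp can shift a score by at most one point and only for subjects whose
#' rounded score lands exactly on the wrong side).
#'
#' All randomness flows from `spec$seed`: clinical covariates are drawn
#' first under the master seed, then each subject's time series uses its own
#' seed drawn from the master stream, so cohorts are reproducible
#' subject-by-subject.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `fc_cohort`: a list with elements
#'   `time_series` (named list of time-series matrices), `clinical` (tibble
#'   with columns `subject_id`, `group`, `age`, `sex`, `hamd17_pre`,
#'   `hamd17_post`, `hama_pre`, `hama_post`, `reduction_rate`, `responder`)
#'   and `ground_truth` (the two group correlation matrices, the module
#'   assignment and the spec).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_responders = 3, n_nonresponders = 3,
#'                                    n_rois = 12, n_timepoints = 40,
#'                                    n_modules = 3, seed = 7))
#' coh$clinical
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_r <- spec$n_responders
  n_n <- spec$n_nonresponders
  n <- n_r + n_n
  group <- c(rep("responder", n_r), rep("nonresponder", n_n))

  covs <- list(responder = make_group_covariance(spec, "responder"),
               nonresponder = make_group_covariance(spec, "nonresponder"))

  rtrunc_norm <- function(n, mean, sd, lower) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lower)) {
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    x
  }

  out <- local_seed(spec$seed, {
    subject_id <- sprintf("sub%03d", seq_len(n))
    if (spec$confound_age_sex) {
      age <- ifelse(group == "responder", sample(13:18, n, TRUE),
                    sample(14:18, n, TRUE))
      sex <- ifelse(group == "responder",
                    rbinom(n, 1, 0.4), rbinom(n, 1, 0.7))
    } else {
      age <- sample(13:18, n, replace = TRUE)
      sex <- rbinom(n, 1, 0.5)
    }
    hamd_pre <- round(rtrunc_norm(n, spec$hamd_pre_mean, spec$hamd_pre_sd, 8))
    hama_pre <- round(rtrunc_norm(n, spec$hama_pre_mean, spec$hama_pre_sd, 1))
    is_resp <- group == "responder"
    lo <- ifelse(is_resp, spec$responder_reduction_range[1],
                 spec$nonresponder_reduction_range[1])
    hi <- ifelse(is_resp, spec$responder_reduction_range[2],
                 spec$nonresponder_reduction_range[2])
    u <- runif(n, lo, hi)
    u_hama <- runif(n, lo, hi)
    hamd_post <- round(hamd_pre * (1 - u))
    # clamp so the derived >= 50% label always matches the generating group
    boundary <- floor(hamd_pre / 2)
    hamd_post[is_resp] <- pmin(hamd_post[is_resp], boundary[is_resp])
    hamd_post[!is_resp] <- pmax(hamd_post[!is_resp], boundary[!is_resp] + 1L)
    hamd_post <- pmax(hamd_post, 0)
    hama_post <- pmax(round(hama_pre * (1 - u_hama)), 0)
    subject_seed <- sample.int(.Machine$integer.max - 1L, n)
    list(clinical = tibble::tibble(
           subject_id = subject_id,
           group = factor(group, levels = c("responder", "nonresponder")),
           age = as.integer(age),
           sex = factor(ifelse(sex == 1, "female", "male"),
                        levels = c("male", "female")),
           hamd17_pre = as.integer(hamd_pre),
           hamd17_post = as.integer(hamd_post),
           hama_pre = as.integer(hama_pre),
           hama_post = as.integer(hama_post)),
         subject_seed = subject_seed)
  })

  clinical <- label_responders(out$clinical)
  derived <- ifelse(clinical$responder, "responder", "nonresponder")
  if (!identical(derived, as.character(clinical$group))) {
    stop("internal error: derived responder labels disagree with generating groups",
         call. = FALSE)
  }

  ts <- purrr::map2(seq_len(n), as.character(clinical$group), function(i, g) {
    simulate_subject_timeseries(covs[[g]], spec$n_timepoints,
                                noise_sd = spec$subject_noise_sd,
                                seed = out$subject_seed[i],
                                subject_id = clinical$subject_id[i])
  })
  names(ts) <- clinical$subject_id

  structure(list(time_series = ts,
                 clinical = clinical,
                 ground_truth = list(covariances = covs,
                                     modules = module_assignment(spec$n_rois, spec$n_modules),
                                     spec = spec)),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  tab <- table(x$clinical$group)
  cat(sprintf("<fc_cohort> %d subjects (%s)\n", nrow(x$clinical),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  d <- dim(x$time_series[[1]])
  cat(sprintf("  time series: %d x %d (timepoints x ROIs) per subject\n", d[1], d[2]))
  invisible(x)
}
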