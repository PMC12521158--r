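#' Functional connectivity matrix from ROI time series
#'
#' Computes the Pearson correlation between every pair of regional time
#' series, the standard weighted substrate of a functional brain network.
#' The diagonal is stored as zero: self-connections are never edges in the
#' thresholded networks, and zeroing them up front removes a special case
#' from the sparsity thresholding.
#'
#' @param ts Numeric matrix (or data frame) with timepoints in rows and ROIs
#'   in columns; column names are used as ROI labels.
#' @param subject_id Optional identifier; defaults to the `subject_id`
#'   attribute of `ts` when present.
#' @return A symmetric N x N numeric matrix with zero diagonal, ROI labels
#'   as dimnames and attribute `subject_id`.
#' @export
#' @examples
#' ts <- simulate_subject_timeseries(diag(5), n_timepoints = 40, seed = 1)
#' fc <- compute_fc_matrix(ts)
#' range(fc)
compute_fc_matrix <- function(ts, subject_id = NULL) {
  subject_id <- subject_id %||% attr(ts, "subject_id")
  x <- as.matrix(ts)
  storage.mode(x) <- "double"
  n <- ncol(x)
  labels <- colnames(x) %||% default_roi_labels(n)
  if (nrow(x) < 3L) {
    stop("time series must have at least 3 timepoints", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("time series contains missing values", call. = FALSE)
  }
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant time series for ROI(s): %s",
                 paste(labels[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  dimnames(r) <- list(labels, labels)
  attr(r, "subject_id") <- subject_id
  r
}

#' Link-weight distribution of a connectivity matrix
#'
#' Returns the strengths of all functional connections: the N(N-1)/2
#' strictly-upper-triangle correlation values, in row-major (i < j) order.
#' By default all weights of the full weighted matrix are returned; set
#' `sparsity` to restrict to the connections surviving binarization at that
#' threshold.
#'
#' @param fc Connectivity matrix from [compute_fc_matrix()].
#' @param sparsity Optional sparsity threshold in (0, 1); when given, only
#'   weights of edges retained by [binarize_at_sparsity()] are returned.
#' @return Numeric vector of length N(N-1)/2 (or the number of retained
#'   edges).
#' @export
#' @examples
#' fc <- matrix(0.5, 3, 3); diag(fc) <- 0
#' link_weight_distribution(fc)
link_weight_distribution <- function(fc, sparsity = NULL) {
  w <- upper_values(fc)
  if (!is.null(sparsity)) {
    g <- binarize_at_sparsity(fc, sparsity)
    keep <- upper_values(g$adjacency) == 1L
    w <- w[keep]
  }
  w
}
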