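# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# funnel through this, so a single integer seed pins down every draw.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# round-half-up, used for edge counts so they are bit-reproducible
# (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

# strictly-upper-triangle index pairs in row-major (i < j) order
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

# extract strictly-upper-triangle values in row-major (i < j) order
upper_values <- function(m) {
  t(m)[lower.tri(m)]
}

# trapezoidal rule
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2)
}

# default ROI labels: packaged AAL-90 abbreviations when n = 90, else ROI%03d
default_roi_labels <- function(n) {
  if (n == 90L) {
    aal90_labels()$label
  } else {
    sprintf("ROI%03d", seq_len(n))
  }
}

#' Node labels of the 90-region AAL parcellation
#'
#' Returns the packaged list of the 90 cerebral regions of the automated
#' anatomical labeling (AAL) atlas commonly used as connectome nodes, with
#' the conventional abbreviations (e.g. `MFG.L`, `HIP.L`, `IPL.R`).
#'
#' @return A tibble with columns `index`, `label` (abbreviation), `hemisphere`
#'   and `region` (full name).
#' @export
#' @examples
#' aal90_labels()
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "fcresponse")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
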