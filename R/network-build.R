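#' Sparsity threshold grid
#'
#' The ordered set of network densities at which a weighted connectivity
#' matrix is binarized. The default grid spans 0.10 to 0.34 in steps of
#' 0.01 (25 thresholds), a range over which group networks stay estimable
#' while avoiding both fragmentation (too sparse) and near-random topology
#' (too dense).
#'
#' @param min,max,step Grid limits and increment, all proportions in (0, 1).
#' @return A strictly increasing numeric vector of class `sparsity_grid`.
#' @export
#' @examples
#' length(sparsity_grid())  # 25
sparsity_grid <- function(min = 0.10, max = 0.34, step = 0.01) {
  stopifnot(min > 0, max < 1, min <= max, step > 0)
  s <- round(seq(min, max, by = step), 10)
  structure(s, class = c("sparsity_grid", "numeric"))
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Ranks the N(N-1)/2 upper-triangle weights and keeps the top
#' `round(s * N(N-1)/2)` as edges of an undirected binary graph (round half
#' up, so edge counts are bit-reproducible). Ranking is by signed value by
#' default, so the strongest positive correlations become edges first and
#' negative correlations enter last; set `rank_by = "absolute"` to rank by
#' magnitude instead. Ties at the cut are broken deterministically by
#' ascending (i, j) lexicographic order.
#'
#' @param fc Symmetric weighted matrix (zero diagonal).
#' @param s Sparsity in (0, 1).
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return An object of class `binary_graph`: list with `adjacency`
#'   (0/1 integer matrix with ROI dimnames), `sparsity` and `n_edges`.
#' @export
#' @examples
#' fc <- compute_fc_matrix(simulate_subject_timeseries(diag(10), 30, seed = 1))
#' g <- binarize_at_sparsity(fc, 0.2)
#' g$n_edges
binarize_at_sparsity <- function(fc, s, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  stopifnot(s > 0, s < 1)
  n <- nrow(fc)
  m <- n * (n - 1L) / 2L
  k <- round_half_up(s * m)
  if (k == 0) {
    stop(sprintf("sparsity %g keeps no edges on %d nodes (empty graph)", s, n),
         call. = FALSE)
  }
  if (k >= m) {
    warning(sprintf("sparsity %g keeps all %d node pairs (complete graph)", s, m))
    k <- m
  }
  w <- upper_values(fc)
  key <- if (rank_by == "signed") w else abs(w)
  ord <- order(-key, seq_along(w))  # ties -> ascending row-major (i, j)
  keep <- ord[seq_len(k)]
  pairs <- upper_pairs(n)
  adj <- matrix(0L, n, n)
  idx <- cbind(pairs$i[keep], pairs$j[keep])
  adj[idx] <- 1L
  adj[idx[, 2:1, drop = FALSE]] <- 1L
  dimnames(adj) <- dimnames(fc)
  binary_graph(adj, sparsity = s)
}

#' Construct a binary graph object
#'
#' Low-level constructor wrapping a 0/1 adjacency matrix; used by
#' [binarize_at_sparsity()] and by tests/fixtures.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param sparsity Achieved edge density; computed from the matrix when
#'   omitted.
#' @return A `binary_graph`.
#' @export
binary_graph <- function(adjacency, sparsity = NULL) {
  adj <- as.matrix(adjacency)
  storage.mode(adj) <- "integer"
  n <- nrow(adj)
  stopifnot(ncol(adj) == n, all(adj %in% c(0L, 1L)))
  if (any(diag(adj) != 0L)) stop("adjacency has self-loops", call. = FALSE)
  if (!identical(adj, t(adj))) stop("adjacency is not symmetric", call. = FALSE)
  n_edges <- sum(adj) / 2L
  structure(list(adjacency = adj,
                 sparsity = sparsity %||% (n_edges / (n * (n - 1) / 2)),
                 n_edges = as.integer(n_edges)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %.3f)\n",
              nrow(x$adjacency), x$n_edges, x$sparsity))
  invisible(x)
}

#' Threshold a connectivity matrix across the sparsity sweep
#'
#' Applies [binarize_at_sparsity()] at every threshold of the grid. Because
#' thresholding is rank-based, the edge sets are nested: the graph at a
#' lower sparsity is a subgraph of the graph at any higher sparsity.
#'
#' @inheritParams binarize_at_sparsity
#' @param grid A [sparsity_grid()].
#' @return A list of `binary_graph` objects, one per threshold, named by
#'   threshold.
#' @export
sweep_graphs <- function(fc, grid = sparsity_grid(), rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  out <- purrr::map(as.numeric(grid), function(s) {
    binarize_at_sparsity(fc, s, rank_by = rank_by)
  })
  names(out) <- format(as.numeric(grid))
  out
}

#' Degree distribution of a binary graph
#'
#' The degree of a node is the number of connections it possesses within
#' the binary network; this returns the per-node degree vector (its sum is
#' twice the edge count).
#'
#' @param g A `binary_graph`.
#' @return Named integer vector of node degrees.
#' @export
#' @examples
#' star <- matrix(0L, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1L
#' degree_distribution(binary_graph(star))
degree_distribution <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  deg <- as.integer(rowSums(g$adjacency))
  names(deg) <- rownames(g$adjacency)
  deg
}
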