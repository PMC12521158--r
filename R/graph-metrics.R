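#' Nodal topological metrics of a binary graph
#'
#' Computes, for every node: degree centrality (row sum of the adjacency),
#' clustering coefficient (fraction of the node's neighbour pairs that are
#' connected, 0 for degree < 2), nodal efficiency (mean inverse shortest
#' path length to all other nodes, with unreachable pairs contributing 0)
#' and betweenness centrality (number of shortest paths between other node
#' pairs passing through the node, by Brandes' dependency accumulation,
#' unnormalized).
#'
#' @param g A `binary_graph`.
#' @return A tibble with columns `node`, `degree`, `clustering`,
#'   `nodal_efficiency`, `betweenness`.
#' @export
#' @examples
#' tri <- matrix(1L, 3, 3); diag(tri) <- 0L
#' nodal_metrics(binary_graph(tri))
nodal_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  n <- nrow(adj)
  d <- cpp_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  tibble::tibble(
    node = rownames(adj) %||% sprintf("ROI%03d", seq_len(n)),
    degree = as.integer(rowSums(adj)),
    clustering = as.numeric(cpp_clustering(adj)),
    nodal_efficiency = rowSums(inv) / (n - 1),
    betweenness = as.numeric(cpp_betweenness(adj))
  )
}

#' Global topological metrics of a binary graph
#'
#' Computes the standard global connectome metrics:
#' * `Cp` — mean nodal clustering coefficient;
#' * `Lp` — characteristic path length, averaged over connected ordered
#'   pairs only (unreachable pairs are excluded, which matters on
#'   fragmented low-sparsity graphs);
#' * `Eglob` — global efficiency, the mean of inverse shortest path lengths
#'   over all ordered pairs (1/Inf = 0 for unreachable pairs);
#' * `Eloc` — local efficiency, the mean over nodes of the global
#'   efficiency of each node's neighbour subgraph (0 for degree < 2);
#' * `gamma`, `lambda`, `sigma` — Cp and Lp normalized by their means over
#'   degree-preserving null networks, and the small-worldness scalar
#'   `sigma = gamma / lambda`; reported as `NA` when no nulls are supplied;
#' * `assortativity` — Pearson correlation of degrees across edge
#'   endpoints (Newman's degree-degree correlation);
#' * `modularity` — Q of the best partition over `n_runs` seeded runs of
#'   greedy (Louvain) modularity optimization.
#'
#' @param g A `binary_graph` with at least one edge.
#' @param nulls Optional list of degree-matched null `binary_graph`s from
#'   [generate_null_networks()], used for `gamma`/`lambda`/`sigma`.
#' @param n_runs Community-detection restarts; the best (highest-Q)
#'   partition is kept, so Q is nondecreasing in `n_runs`.
#' @param seed Seed for the community-detection restarts.
#' @return A one-row tibble with columns `Cp`, `Lp`, `Eglob`, `Eloc`,
#'   `gamma`, `lambda`, `sigma`, `assortativity`, `modularity`.
#' @export
#' @examples
#' k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
#' global_metrics(binary_graph(k4))
global_metrics <- function(g, nulls = NULL, n_runs = 10, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  n <- nrow(adj)
  if (g$n_edges == 0) stop("graph has no edges", call. = FALSE)

  cc <- cpp_clustering(adj)
  cp <- mean(cc)
  d <- cpp_distances(adj)
  off <- row(d) != col(d)
  finite_off <- off & is.finite(d)
  lp <- mean(d[finite_off])
  inv <- ifelse(is.finite(d) & off, 1 / d, 0)
  eglob <- sum(inv) / (n * (n - 1))
  eloc <- mean(cpp_local_efficiency(adj))
  assort <- assortativity_degree(adj)
  q <- best_modularity(g, n_runs = n_runs, seed = seed)

  if (!is.null(nulls) && length(nulls) > 0) {
    null_stats <- vapply(nulls, function(ng) cpp_cp_lp(ng$adjacency), numeric(2))
    gamma <- cp / mean(null_stats[1, ])
    lambda <- lp / mean(null_stats[2, ])
    sigma <- gamma / lambda
  } else {
    gamma <- lambda <- sigma <- NA_real_
  }

  tibble::tibble(Cp = cp, Lp = lp, Eglob = eglob, Eloc = eloc,
                 gamma = gamma, lambda = lambda, sigma = sigma,
                 assortativity = assort, modularity = q)
}

# Newman's assortativity as the Pearson correlation of degrees across the
# two endpoints of every edge, counting both orientations.
assortativity_degree <- function(adj) {
  deg <- rowSums(adj)
  pairs <- which(adj == 1L, arr.ind = TRUE)  # both orientations
  if (nrow(pairs) == 0) return(NA_real_)
  x <- deg[pairs[, 1]]
  y <- deg[pairs[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Modularity Q of a given partition
#'
#' Newman's modularity \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)}: for each
#' community, the fraction of edges falling inside it minus the fraction
#' expected under a degree-matched random graph.
#'
#' @param adjacency 0/1 symmetric matrix (or a `binary_graph`).
#' @param membership Integer community assignment per node.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(adjacency, membership) {
  if (inherits(adjacency, "binary_graph")) adjacency <- adjacency$adjacency
  m <- sum(adjacency) / 2
  if (m == 0) return(NA_real_)
  deg <- rowSums(adjacency)
  q <- 0
  for (c_id in unique(membership)) {
    idx <- membership == c_id
    e_c <- sum(adjacency[idx, idx, drop = FALSE]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Best-of-n_runs greedy modularity optimization. Community detection is the
# one step delegated to igraph (Louvain); Q itself is recomputed with
# modularity_q() on the returned membership. Runs use seeds seed+1..seed+n,
# so increasing n_runs extends (never replaces) the searched set.
best_modularity <- function(g, n_runs = 10, seed = 1L) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  best <- -Inf
  for (r in seq_len(n_runs)) {
    memb <- local_seed(seed + r, igraph::membership(igraph::cluster_louvain(ig)))
    q <- modularity_q(g$adjacency, as.integer(memb))
    if (q > best) best <- q
  }
  best
}

#' Degree-preserving null networks
#'
#' Produces randomized reference graphs sharing the exact degree sequence
#' of `g` via double-edge swaps (Maslov-Sneppen rewiring): repeatedly pick
#' two edges and exchange their endpoints, rejecting swaps that would
#' create self-loops or duplicate edges. Each null attempts
#' `swaps_per_edge * n_edges` swaps. Used to normalize clustering and path
#' length into `gamma`, `lambda` and the small-worldness `sigma`.
#'
#' @param g A `binary_graph` with at least 2 edges.
#' @param n_nulls Ensemble size (default 100).
#' @param seed Integer seed; the whole ensemble is drawn from one RNG
#'   stream seeded with it, so the same seed reproduces every null.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return List of `binary_graph` objects with identical degree sequences.
#' @export
generate_null_networks <- function(g, n_nulls = 100, seed = 1L, swaps_per_edge = 10) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$n_edges < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  attempts <- as.integer(swaps_per_edge * g$n_edges)
  total_swaps <- 0L
  out <- local_seed(seed, {
    purrr::map(seq_len(n_nulls), function(i) {
      res <- cpp_double_edge_swap(g$adjacency, attempts)
      total_swaps <<- total_swaps + res$n_swaps
      dimnames(res$adjacency) <- dimnames(g$adjacency)
      binary_graph(res$adjacency, sparsity = g$sparsity)
    })
  })
  if (total_swaps == 0L) {
    warning("no valid double-edge swap exists for this graph; nulls are copies of it")
  }
  out
}

#' Area under a metric curve across the sparsity sweep
#'
#' Integrates a per-threshold metric curve over the sparsity grid by the
#' trapezoidal rule, yielding a threshold-insensitive summary (e.g. a
#' constant curve of 1 over the default 0.10-0.34 grid integrates to 0.24).
#'
#' @param values Metric values, one per threshold.
#' @param grid The matching [sparsity_grid()].
#' @return The trapezoidal integral, a single number.
#' @export
#' @examples
#' auc_over_sweep(rep(1, 25), sparsity_grid())  # 0.24
auc_over_sweep <- function(values, grid = sparsity_grid()) {
  if (length(values) != length(grid)) {
    stop(sprintf("length mismatch: %d values vs %d thresholds",
                 length(values), length(grid)), call. = FALSE)
  }
  stopifnot(!is.unsorted(as.numeric(grid), strictly = TRUE))
  trapz(as.numeric(grid), values)
}

#' Metric curves and AUC summaries for one subject
#'
#' The per-subject pipeline stage: thresholds the connectivity matrix
#' across the sparsity grid, computes all global and nodal metrics on each
#' binary graph (with degree-preserving null normalization for
#' `gamma`/`lambda`/`sigma`), and integrates every metric curve over the
#' sweep.
#'
#' @param fc Connectivity matrix from [compute_fc_matrix()].
#' @param grid A [sparsity_grid()].
#' @param n_nulls Null networks per threshold (default 100).
#' @param n_runs Community-detection restarts per threshold.
#' @param seed Seed; nulls at threshold t use a seed derived as
#'   `seed + 1000 * t_index`.
#' @param subject_id Identifier; defaults to the matrix attribute.
#' @return An object of class `metric_curves`: list with `subject_id`,
#'   `curves` (tibble: `subject_id`, `metric`, `scope`, `node`,
#'   `threshold`, `value`) and `auc` (tibble: `subject_id`, `metric`,
#'   `scope`, `node`, `auc`).
#' @export
metrics_for_subject <- function(fc, grid = sparsity_grid(), n_nulls = 100,
                                n_runs = 10, seed = 1L, subject_id = NULL) {
  subject_id <- subject_id %||% attr(fc, "subject_id") %||% "subject"
  graphs <- sweep_graphs(fc, grid)
  thresholds <- as.numeric(grid)

  per_threshold <- purrr::map2(graphs, seq_along(graphs), function(g, t_idx) {
    gm <- global_metrics(g, nulls = NULL, n_runs = n_runs,
                         seed = seed + 1000L * t_idx)
    # null normalization via the single-call C++ ensemble; consumes the RNG
    # stream exactly as generate_null_networks() under the same seed
    null_stats <- local_seed(seed + 1000L * t_idx,
                             cpp_null_cp_lp(g$adjacency, n_nulls, 10L))
    gm$gamma <- gm$Cp / mean(null_stats[, 1])
    gm$lambda <- gm$Lp / mean(null_stats[, 2])
    gm$sigma <- gm$gamma / gm$lambda
    nm <- nodal_metrics(g)
    glob <- tidyr::pivot_longer(gm, cols = dplyr::everything(),
                                names_to = "metric", values_to = "value")
    glob$scope <- "global"
    glob$node <- NA_character_
    noda <- tidyr::pivot_longer(nm, cols = c("degree", "clustering",
                                             "nodal_efficiency", "betweenness"),
                                names_to = "metric", values_to = "value")
    noda$scope <- "nodal"
    dplyr::bind_rows(glob[, c("metric", "scope", "node", "value")],
                     noda[, c("metric", "scope", "node", "value")]) |>
      dplyr::mutate(threshold = thresholds[t_idx])
  })

  curves <- dplyr::bind_rows(per_threshold)
  curves$subject_id <- subject_id
  curves <- curves[, c("subject_id", "metric", "scope", "node", "threshold", "value")]

  auc <- curves |>
    dplyr::group_by(.data$subject_id, .data$metric, .data$scope, .data$node) |>
    dplyr::arrange(.data$threshold, .by_group = TRUE) |>
    dplyr::summarise(auc = auc_over_sweep(.data$value, grid), .groups = "drop")

  structure(list(subject_id = subject_id,
                 curves = tibble::as_tibble(curves),
                 auc = auc),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat(sprintf("<metric_curves> subject %s: %d thresholds, %d metric series\n",
              x$subject_id, length(unique(x$curves$threshold)),
              nrow(x$auc)))
  invisible(x)
}

#' @rdname metrics_for_subject
#' @param x A `metric_curves` object.
#' @param ... Unused.
#' @export
tidy.metric_curves <- function(x, ...) x$auc

#' AUC metric table for a whole cohort
#'
#' Runs [metrics_for_subject()] for every subject of a cohort and binds the
#' AUC summaries into one tidy table with the clinical group attached —
#' the input to [compare_group_metrics()].
#'
#' @param cohort An `fc_cohort` from [simulate_cohort()], or a named list of
#'   connectivity matrices plus a `clinical` tibble.
#' @param grid,n_nulls,n_runs,seed Passed to [metrics_for_subject()];
#'   subject `i` uses seed `seed + 100000 * i`.
#' @param fc_list Optional precomputed list of connectivity matrices (by
#'   default computed from the cohort's time series).
#' @param progress Print one line per subject.
#' @return A tibble: `subject_id`, `group`, `metric`, `scope`, `node`,
#'   `auc`.
#' @export
cohort_metrics <- function(cohort, grid = sparsity_grid(), n_nulls = 100,
                           n_runs = 10, seed = 1L, fc_list = NULL,
                           progress = FALSE) {
  clinical <- cohort$clinical
  if (is.null(fc_list)) {
    fc_list <- purrr::map(cohort$time_series, compute_fc_matrix)
  }
  stopifnot(all(clinical$subject_id %in% names(fc_list)))
  res <- purrr::imap(fc_list[clinical$subject_id], function(fc, sid) {
    i <- match(sid, clinical$subject_id)
    if (progress) message(sprintf("metrics: %s (%d/%d)", sid, i, nrow(clinical)))
    tidy(metrics_for_subject(fc, grid = grid, n_nulls = n_nulls,
                             n_runs = n_runs,
                             seed = seed + 100000L * i, subject_id = sid))
  })
  dplyr::bind_rows(res) |>
    dplyr::left_join(clinical[, c("subject_id", "group")], by = "subject_id") |>
    dplyr::relocate("group", .after = "subject_id")
}
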