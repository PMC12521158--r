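# Graph fixtures and independent oracles used across the suite.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

complete_adj <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

path_adj <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

star_adj <- function(n) {
  adj_from_edges(n, lapply(2:n, function(i) c(1, i)))
}

# ring lattice: each node connected to k/2 neighbours on each side
ring_lattice_adj <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

random_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut[runif(length(ut)) < p]] <- 1L
  a + t(a)
}

# random symmetric weight matrix (a stand-in connectivity matrix)
random_fc <- function(n) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- runif(sum(ut), -1, 1)
  w <- w + t(w)
  diag(w) <- 0
  w
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# independent Eloc reference: induced neighbour subgraph efficiency
# composed from igraph primitives
igraph_local_efficiency_induced <- function(adj) {
  ig <- as_igraph(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1L)
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(ig, nb)
    e <- igraph::global_efficiency(sub)
    if (is.nan(e)) 0 else e
  }, numeric(1))
}

# exhaustive betweenness by simple-path enumeration (feasible for n <= 8)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  all_paths <- function(s, t) {
    res <- list()
    walk <- function(v, path) {
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ] == 1L)) {
        if (!(w %in% path)) walk(w, c(path, w))
      }
    }
    walk(s, s)
    res
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      nsp <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / nsp
      }
    }
  }
  bc
}

# exact permutation-test p-value by exhaustive enumeration of partitions
exact_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  idx <- utils::combn(n, length(a))
  obs <- mean(a) - mean(b)
  diffs <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# internal helpers referenced by tests
upper_values <- fcresponse:::upper_values
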