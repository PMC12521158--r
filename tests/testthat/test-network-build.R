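test_that("binarization keeps the top-ranked edges with deterministic ties", {
  # worked example: rank top 2 of 6 weights
  w <- matrix(0, 4, 4)
  w[1, 2] <- .9; w[1, 3] <- .8; w[1, 4] <- .1
  w[2, 3] <- .2; w[2, 4] <- .3; w[3, 4] <- .4
  w <- w + t(w)
  g <- binarize_at_sparsity(w, 1 / 3)
  expect_equal(g$n_edges, 2L)
  expect_equal(which(upper_values(g$adjacency) == 1L), c(1L, 2L))  # (1,2), (1,3)

  # all weights equal: lexicographically first pairs win
  eq <- matrix(1, 4, 4); diag(eq) <- 0
  g <- binarize_at_sparsity(eq, 0.5)
  expect_equal(g$n_edges, 3L)
  expect_equal(which(upper_values(g$adjacency) == 1L), 1:3)  # (1,2),(1,3),(1,4)

  # keep-all threshold gives the complete graph (with a warning)
  m <- 6
  expect_warning(g <- binarize_at_sparsity(w, (m - 0.5) / m), "complete")
  expect_equal(g$n_edges, 6L)
  expect_error(binarize_at_sparsity(w, 1e-4), "empty")
})

test_that("achieved sparsity is within one edge of the request", {
  set.seed(21)
  fc <- random_fc(25)
  m <- 25 * 24 / 2
  for (s in as.numeric(sparsity_grid())) {
    g <- binarize_at_sparsity(fc, s)
    expect_lte(abs(g$n_edges / m - s), 1 / m)
  }
})

test_that("binarization is invariant under strictly increasing weight transforms", {
  set.seed(22)
  fc <- random_fc(15)
  g1 <- binarize_at_sparsity(fc, 0.25)
  g2 <- binarize_at_sparsity(atan(fc) * 2, 0.25)   # strictly increasing, sign-preserving
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("sweep produces one nested graph per threshold", {
  set.seed(23)
  fc <- random_fc(20)
  graphs <- sweep_graphs(fc, sparsity_grid())
  expect_length(graphs, 25)
  for (i in seq_len(length(graphs) - 1)) {
    a <- graphs[[i]]$adjacency
    b <- graphs[[i + 1]]$adjacency
    expect_true(all(b[a == 1L] == 1L))  # edge sets nested
  }
  single <- sweep_graphs(fc, sparsity_grid(0.2, 0.2, 0.01))
  expect_length(single, 1)
})

test_that("degree distribution satisfies the handshake lemma and closed forms", {
  expect_equal(unname(degree_distribution(binary_graph(star_adj(4)))),
               c(3L, 1L, 1L, 1L))
  expect_equal(unname(degree_distribution(binary_graph(complete_adj(5)))),
               rep(4L, 5))
  set.seed(24)
  for (i in 1:5) {
    g <- binary_graph(random_adj(12, runif(1, 0.2, 0.7)))
    expect_equal(sum(degree_distribution(g)), 2L * g$n_edges)
  }
})
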