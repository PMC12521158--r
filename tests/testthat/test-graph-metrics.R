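test_that("closed-form fixtures give exact metric values", {
  for (n in c(3, 5, 7)) {
    gm <- global_metrics(binary_graph(complete_adj(n)), n_runs = 1, seed = 1)
    expect_equal(gm$Cp, 1)
    expect_equal(gm$Lp, 1)
    expect_equal(gm$Eglob, 1)
    expect_equal(gm$Eloc, 1)
  }

  # path a-b-c
  p3 <- binary_graph(path_adj(3))
  gm <- global_metrics(p3, n_runs = 1, seed = 1)
  expect_equal(gm$Lp, 4 / 3)
  expect_equal(gm$Eglob, 5 / 6)
  nm <- nodal_metrics(p3)
  expect_equal(nm$betweenness, c(0, 1, 0))
  expect_equal(nm$nodal_efficiency, c(0.75, 1, 0.75))

  # triangle
  nm <- nodal_metrics(binary_graph(complete_adj(3)))
  expect_equal(nm$clustering, rep(1, 3))
  expect_equal(nm$nodal_efficiency, rep(1, 3))
  expect_equal(nm$betweenness, rep(0, 3))

  # star on 5 nodes: center routes all leaf pairs; assortativity -1
  s5 <- binary_graph(star_adj(5))
  expect_equal(nodal_metrics(s5)$betweenness, c(choose(4, 2), 0, 0, 0, 0))
  gm <- suppressWarnings(global_metrics(s5, n_runs = 1, seed = 1))
  expect_equal(gm$assortativity, -1)
  # leaves have degree 1: betweenness 0, clustering 0
  expect_equal(nodal_metrics(s5)$clustering, rep(0, 5))
})

test_that("modularity Q matches the hand-computed two-clique partition", {
  a <- matrix(0L, 8, 8)
  a[1:4, 1:4] <- complete_adj(4)
  a[5:8, 5:8] <- complete_adj(4)
  expect_equal(modularity_q(a, rep(1:2, each = 4)), 0.5)
  # merging everything into one community wipes out the modular structure
  expect_equal(modularity_q(a, rep(1, 8)), 0)
})

test_that("metrics agree with the igraph reference on random graphs", {
  set.seed(31)
  for (i in 1:30) {
    a <- random_adj(sample(5:30, 1), runif(1, 0.15, 0.6))
    g <- binary_graph(a)
    if (g$n_edges < 2) next
    ig <- as_igraph(a)
    nm <- nodal_metrics(g)
    expect_equal(nm$degree, unname(igraph::degree(ig)))
    expect_equal(nm$clustering,
                 igraph::transitivity(ig, type = "local", isolates = "zero"),
                 tolerance = 1e-9)
    expect_equal(nm$betweenness, unname(igraph::betweenness(ig)),
                 tolerance = 1e-9)
    gm <- suppressWarnings(global_metrics(g, n_runs = 1, seed = 1))
    expect_equal(gm$Eglob, igraph::global_efficiency(ig), tolerance = 1e-9)
    expect_equal(gm$Eloc, mean(igraph_local_efficiency_induced(a)),
                 tolerance = 1e-9)
    if (!is.na(gm$assortativity)) {
      expect_equal(gm$assortativity, igraph::assortativity_degree(ig),
                   tolerance = 1e-9)
    }
  }
})

test_that("betweenness matches exhaustive path enumeration on tiny graphs", {
  set.seed(32)
  for (i in 1:8) {
    a <- random_adj(sample(4:8, 1), runif(1, 0.3, 0.8))
    expect_equal(nodal_metrics(binary_graph(a))$betweenness,
                 brute_betweenness(a), tolerance = 1e-9)
  }
})

test_that("null networks preserve degrees, are seeded, and destroy lattice clustering", {
  rl <- binary_graph(ring_lattice_adj(20, 4))
  nulls <- generate_null_networks(rl, n_nulls = 20, seed = 7)
  deg <- degree_distribution(rl)
  for (ng in nulls) {
    expect_equal(degree_distribution(ng), deg)
  }
  null_cp <- vapply(nulls, function(ng) mean(nodal_metrics(ng)$clustering),
                    numeric(1))
  lattice_cp <- mean(nodal_metrics(rl)$clustering)
  expect_lt(mean(null_cp), lattice_cp)

  nulls2 <- generate_null_networks(rl, n_nulls = 20, seed = 7)
  expect_identical(purrr::map(nulls, "adjacency"), purrr::map(nulls2, "adjacency"))

  # star admits no valid swap: copies plus a warning
  expect_warning(ns <- generate_null_networks(binary_graph(star_adj(5)),
                                              n_nulls = 3, seed = 1),
                 "copies")
  expect_identical(ns[[1]]$adjacency, star_adj(5))
})

test_that("AUC integration is the trapezoid rule and is linear", {
  expect_equal(auc_over_sweep(rep(1, 25), sparsity_grid()), 0.24)
  expect_equal(auc_over_sweep(rep(0, 25), sparsity_grid()), 0)
  g3 <- sparsity_grid(0.1, 0.3, 0.1)
  expect_equal(auc_over_sweep(as.numeric(g3), g3), 0.04)
  expect_error(auc_over_sweep(1:3, sparsity_grid()), "mismatch")

  set.seed(33)
  v <- runif(25); w <- runif(25)
  expect_equal(auc_over_sweep(2 * v + 3 * w, sparsity_grid()),
               2 * auc_over_sweep(v, sparsity_grid()) +
                 3 * auc_over_sweep(w, sparsity_grid()),
               tolerance = 1e-12)
})

test_that("per-subject metric curves are complete, deterministic and self-consistent", {
  set.seed(34)
  ts <- simulate_subject_timeseries(diag(20), 80, seed = 5, subject_id = "s1")
  fc <- compute_fc_matrix(ts)
  grid <- sparsity_grid(0.15, 0.30, 0.05)
  mc <- metrics_for_subject(fc, grid, n_nulls = 8, n_runs = 3, seed = 2)
  expect_s3_class(mc$curves, "tbl_df")
  # 9 global + 4 nodal x 20 nodes, per threshold
  expect_equal(nrow(mc$curves), (9 + 4 * 20) * length(grid))
  expect_equal(nrow(mc$auc), 9 + 4 * 20)
  # sigma = gamma / lambda at every threshold, exactly
  glob <- tidyr::pivot_wider(
    dplyr::filter(mc$curves, scope == "global"),
    id_cols = "threshold", names_from = "metric", values_from = "value")
  expect_equal(glob$sigma, glob$gamma / glob$lambda)
  cp_auc <- mc$auc$auc[mc$auc$metric == "Cp"]
  expect_gt(cp_auc, 0)
  expect_lt(cp_auc, diff(range(as.numeric(grid))))

  mc2 <- metrics_for_subject(fc, grid, n_nulls = 8, n_runs = 3, seed = 2)
  expect_identical(mc$curves, mc2$curves)
})

test_that("best-of-runs modularity never decreases with more restarts", {
  set.seed(35)
  g <- binary_graph(random_adj(40, 0.15))
  q2 <- fcresponse:::best_modularity(g, n_runs = 2, seed = 9)
  q6 <- fcresponse:::best_modularity(g, n_runs = 6, seed = 9)
  q12 <- fcresponse:::best_modularity(g, n_runs = 12, seed = 9)
  expect_gte(q6, q2)
  expect_gte(q12, q6)
})
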