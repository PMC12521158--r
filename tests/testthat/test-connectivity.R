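test_that("Pearson connectivity matches hand and brute-force computation", {
  # proportional, anti-proportional and the 4-point worked example
  ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
              c = -c(1, 2, 3, 4), d = c(1, 3, 2, 4))
  fc <- compute_fc_matrix(ts)
  expect_equal(fc["a", "b"], 1)
  expect_equal(fc["a", "c"], -1)
  expect_equal(fc["a", "d"], 0.8)
  expect_equal(diag(fc), setNames(rep(0, 4), colnames(ts)))
  expect_identical(fc, t(fc) |> `attr<-`("subject_id", NULL))

  # brute-force covariance/sd agreement on random input
  set.seed(9)
  x <- matrix(rnorm(200), 20, 10)
  fc <- compute_fc_matrix(x)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
      expect_equal(fc[i, j], r, tolerance = 1e-12)
    }
  }
})

test_that("connectivity is invariant to positive affine rescaling of columns", {
  set.seed(4)
  x <- matrix(rnorm(150), 30, 5)
  scaled <- sweep(sweep(x, 2, c(2, 0.5, 10, 1, 3), `*`), 2, c(-1, 4, 0, 2, 7), `+`)
  expect_equal(compute_fc_matrix(x), compute_fc_matrix(scaled), tolerance = 1e-12)
})

test_that("invalid time series are rejected with informative errors", {
  x <- matrix(rnorm(40), 10, 4)
  colnames(x) <- paste0("R", 1:4)
  x[, 3] <- 5
  expect_error(compute_fc_matrix(x), "R3")
  y <- matrix(rnorm(40), 10, 4)
  y[2, 2] <- NA
  expect_error(compute_fc_matrix(y), "missing")
  expect_error(compute_fc_matrix(matrix(rnorm(4), 2, 2)), "3 timepoints")
})

test_that("link-weight distribution returns upper-triangle weights in row-major order", {
  fc <- matrix(0.5, 3, 3)
  diag(fc) <- 0
  expect_equal(link_weight_distribution(fc), c(0.5, 0.5, 0.5))

  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 12
  m[1, 3] <- m[3, 1] <- 13
  m[2, 3] <- m[3, 2] <- 23
  expect_equal(link_weight_distribution(m), c(12, 13, 23))

  set.seed(2)
  for (n in sample(3:20, 5)) {
    expect_length(link_weight_distribution(random_fc(n)), n * (n - 1) / 2)
  }
  expect_length(link_weight_distribution(random_fc(90)), 4005)

  # restricted to edges surviving a sparsity threshold
  fc <- random_fc(10)
  w <- link_weight_distribution(fc, sparsity = 0.2)
  expect_length(w, binarize_at_sparsity(fc, 0.2)$n_edges)
  expect_true(all(w >= sort(upper_tri <- link_weight_distribution(fc), decreasing = TRUE)[length(w)]))
})
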