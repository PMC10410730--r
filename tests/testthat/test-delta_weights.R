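test_that("sample_differences draws exact, deterministic pair differences", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  dx <- sample_differences(X, 25L, seed = 4L)
  expect_equal(nrow(dx$rows), 25L)
  for (r in c(1L, 10L, 25L))
    expect_identical(dx$rows[r, ],
                     X[dx$pair_index[r, 1], ] - X[dx$pair_index[r, 2], ])
  expect_true(all(dx$pair_index[, 1] < dx$pair_index[, 2]))
  expect_identical(dx, sample_differences(X, 25L, seed = 4L))
  # no replacement while distinct pairs remain
  dx2 <- sample_differences(X, 45L, seed = 2L)  # choose(10,2) = 45
  expect_equal(anyDuplicated(dx2$pair_index), 0L)
  # duplicates in X give zero rows without error
  Xd <- X[c(1, 1, 2), ]
  dx3 <- sample_differences(Xd, 3L, seed = 1L)
  expect_true(any(rowSums(abs(dx3$rows)) == 0))
  expect_error(sample_differences(X[1, , drop = FALSE], 1L),
               class = "dm_insufficient_data")
})

test_that("delta_pca matches the SVD oracle with fixed sign convention", {
  set.seed(7)
  X <- matrix(rnorm(200), 40, 5)
  dx <- sample_differences(X, 100L, seed = 3L)
  W <- delta_pca(dx, 3L)
  sv <- svd(dx$rows)
  expect_true(all(abs(diag(W$W %*% sv$v[, 1:3])) > 1 - 1e-8))
  for (i in 1:3) expect_gt(W$W[i, which.max(abs(W$W[i, ]))], 0)
  # orthonormal rows
  G <- W$W %*% t(W$W)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  # rank-1 input
  dx1 <- sample_differences(rbind(0, 2 * diag(5)[1, , drop = FALSE],
                                  -diag(5)[1, , drop = FALSE]), 3L, seed = 1L)
  W1 <- delta_pca(dx1, 1L)
  expect_equal(drop(abs(W1$W)), c(1, 0, 0, 0, 0))
  expect_error(delta_pca(dx, 6L), class = "dm_rank_error")
})

test_that("reconstruction_residual equals the discarded singular value sum", {
  set.seed(8)
  dx <- sample_differences(matrix(rnorm(240), 40, 6), 120L, seed = 5L)
  sv <- svd(dx$rows)
  for (k in c(2L, 4L)) {
    expect_equal(reconstruction_residual(delta_pca(dx, k), dx),
                 sum(sv$d[(k + 1):6]^2), tolerance = 1e-6)
  }
  expect_lt(reconstruction_residual(delta_pca(dx, 6L), dx), 1e-8)
  # residual non-increasing as rows are appended
  r <- vapply(1:5, function(k) reconstruction_residual(delta_pca(dx, k), dx),
              numeric(1))
  expect_true(all(diff(r) <= 1e-10))
})

test_that("delta_pca is the best rank-k subspace among random competitors", {
  set.seed(9)
  dx <- sample_differences(matrix(rnorm(300), 50, 6), 150L, seed = 2L)
  best <- reconstruction_residual(delta_pca(dx, 3L), dx)
  for (i in 1:100) {
    R <- matrix(rnorm(18), 3, 6)
    expect_gte(reconstruction_residual(R, dx) - best, -1e-8)
  }
})

test_that("delta_sd: monotone objective, penalty limits, unit rows", {
  set.seed(10)
  dx <- sample_differences(matrix(rnorm(180), 30, 6), 90L, seed = 6L)
  r <- delta_sd(dx, 4L, lambda = 0.5, n_iter = 25L, seed = 3L)
  expect_true(all(diff(r$objective) <= 1e-8))
  expect_equal(unname(sqrt(rowSums(r$W$W^2))), rep(1, 4), tolerance = 1e-9)
  # lambda = 0 at full rank: residual collapses to zero
  r0 <- delta_sd(dx, 6L, lambda = 0, n_iter = 80L, seed = 3L)
  expect_lt(utils::tail(r0$objective, 1), 1e-8)
  # a huge penalty drives C to zero and the objective to ||DX||^2
  rb <- delta_sd(dx, 4L, lambda = 1e6, n_iter = 5L, seed = 3L)
  expect_equal(unname(max(abs(rb$C))), 0)
  expect_equal(utils::tail(rb$objective, 1), sum(dx$rows^2))
  expect_error(delta_sd(dx, 2L, lambda = -1), class = "dm_parameter_error")
  # constrained solutions can never beat the unconstrained rank-k optimum
  expect_gte(sum((dx$rows - r$C %*% r$W$W)^2) -
               reconstruction_residual(delta_pca(dx, 4L), dx), -1e-8)
})

test_that("delta_pmd honours its constraints and reduces to SVD at no-op bounds", {
  set.seed(11)
  dx <- sample_differences(matrix(rnorm(240), 40, 6), 120L, seed = 8L)
  sv <- svd(dx$rows)
  # no-op bounds: top singular vectors recovered
  p <- delta_pmd(dx, 3L, eps = sqrt(6), delta = sqrt(120), seed = 2L)
  expect_true(all(abs(diag(p$W$W %*% sv$v[, 1:3])) > 1 - 1e-6))
  # active bounds: L1/L2 constraints met within 1e-6
  p2 <- delta_pmd(dx, 3L, eps = 1.5, delta = 5, seed = 2L)
  expect_true(all(sqrt(rowSums(p2$W$W^2)) <= 1 + 1e-6))
  expect_true(all(rowSums(abs(p2$W$W)) <= 1.5 + 1e-6))
  expect_true(all(colSums(abs(p2$U)) <= 5 + 1e-6))
  expect_true(all(abs(sqrt(colSums(p2$U^2)) - 1) < 1e-6))
  # rank-1 closed form: sparse right factor recovered up to sign convention
  u <- rnorm(20); v <- c(3, -4, 0, 0, 0, 0)
  dx1 <- structure(list(rows = outer(u, v), pair_index = cbind(1L, 2L),
                        seed = 1L), class = "difference_matrix")
  p3 <- delta_pmd(dx1, 1L, eps = 7 / 5, delta = sqrt(20), seed = 1L)
  expect_equal(drop(p3$W$W), c(-0.6, 0.8, 0, 0, 0, 0), tolerance = 1e-6)
  expect_error(delta_pmd(dx, 2L, eps = 0.5, delta = 5),
               class = "dm_infeasible_constraint")
  # constrained residual >= unconstrained PCA residual
  expect_gte(sum((dx$rows - p2$C %*% p2$W$W)^2) -
               reconstruction_residual(delta_pca(dx, 3L), dx), -1e-8)
})

test_that("random_projection is seeded Gaussian with the stated moments", {
  W1 <- random_projection(50L, 40L, seed = 5L)
  expect_identical(W1, random_projection(50L, 40L, seed = 5L))
  expect_false(identical(W1$W, random_projection(50L, 40L, seed = 6L)$W))
  expect_lt(abs(mean(W1$W)), 3 / sqrt(2000))         # mean ~ 0
  expect_equal(stats::sd(W1$W), 1 / sqrt(50), tolerance = 0.05)
  expect_equal(dim(random_projection(10L, 0L)$W), c(0L, 10L))
})
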