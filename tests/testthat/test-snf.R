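test_that("scaled exponential kernel matches the hand-evaluated two-point case", {
  # 1-D points 0 and 1, K = 1, mu = 0.5: each point's single neighbor is the
  # other, so eps = (1 + 1 + 1)/3 = 1 and e_12 = exp(-1 / 0.5)
  X <- matrix(c(0, 1), nrow = 1)
  colnames(X) <- c("a", "b")
  E <- affinity_kernel(X, snf_params(mu = 0.5, K = 1))
  expect_equal(E[1, 2], exp(-2))
  expect_equal(diag(E), c(a = 1, b = 1))
})

test_that("kernel is symmetric with unit diagonal and survives duplicates", {
  set.seed(5)
  X <- matrix(rnorm(8 * 12), 8, 12)
  E <- affinity_kernel(X, snf_params(K = 4))
  expect_equal(E, t(E))
  expect_equal(diag(E), rep(1, 12), ignore_attr = TRUE)
  expect_true(all(E >= 0 & E <= 1))

  Xdup <- cbind(X, X[, 1])   # duplicated sample: eps floored, no NaN
  Edup <- affinity_kernel(Xdup, snf_params(K = 4))
  expect_true(all(is.finite(Edup)))
})

test_that("global kernel is row-stochastic with half-diagonal", {
  set.seed(6)
  E <- affinity_kernel(matrix(rnorm(5 * 9), 5, 9), snf_params(K = 3))
  P <- global_kernel(E)
  expect_equal(rowSums(P), rep(1, 9), ignore_attr = TRUE)
  expect_equal(diag(P), rep(0.5, 9), ignore_attr = TRUE)
  # ratio invariance: scaling E leaves P unchanged
  expect_equal(global_kernel(7.3 * E), P)
  # two samples: single off-diagonal entry normalizes to 1/2
  E2 <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  expect_equal(global_kernel(E2), matrix(0.5, 2, 2))
  # disconnected sample is reported
  Ebad <- diag(3)
  expect_error(global_kernel(Ebad), "disconnected")
})

test_that("local kernel keeps the K nearest neighbors plus self", {
  E <- matrix(c(1.0, 0.9, 0.1,
                0.9, 1.0, 0.5,
                0.1, 0.5, 1.0), 3, 3, byrow = TRUE)
  S <- local_kernel(E, K = 1)
  # row 1 keeps {1, 2}; row 3 keeps {3, 2}
  expect_equal(S[1, ], c(1 / 1.9, 0.9 / 1.9, 0))
  expect_equal(S[3, ], c(0, 0.5 / 1.5, 1 / 1.5))
  expect_equal(rowSums(S), rep(1, 3))

  set.seed(7)
  E <- affinity_kernel(matrix(rnorm(4 * 10), 4, 10), snf_params(K = 3))
  for (K in c(1, 5, 9)) {
    S <- local_kernel(E, K)
    expect_equal(rowSums(S), rep(1, 10), ignore_attr = TRUE)
    expect_true(all(rowSums(S > 0) == K + 1))
  }
  # K = n - 1: full row, plain normalization
  S <- local_kernel(E, 9)
  expect_equal(S, E / rowSums(E), ignore_attr = TRUE)
})

test_that("fusion matches an independently coded one-round evaluation", {
  E1 <- matrix(c(1.0, 0.8, 0.3,
                 0.8, 1.0, 0.4,
                 0.3, 0.4, 1.0), 3, 3, byrow = TRUE)
  E2 <- matrix(c(1.0, 0.2, 0.7,
                 0.2, 1.0, 0.5,
                 0.7, 0.5, 1.0), 3, 3, byrow = TRUE)
  A <- snf_fuse(list(E1, E2), snf_params(K = 1, n_iterations = 1))
  A_oracle <- oracle_fuse_one_round(list(E1, E2), K = 1)
  expect_equal(A, A_oracle, tolerance = 1e-12)
})

test_that("fusion is symmetric, order-invariant and permutation-equivariant", {
  set.seed(8)
  E_list <- lapply(1:3, function(v) affinity_kernel(matrix(rnorm(6 * 14), 6, 14),
                                                    snf_params(K = 4)))
  p <- snf_params(K = 4, n_iterations = 5)
  A <- snf_fuse(E_list, p)
  expect_equal(A, t(A), tolerance = 1e-10)
  expect_true(all(A >= 0))
  expect_equal(snf_fuse(rev(E_list), p), A, tolerance = 1e-12)

  perm <- sample(14)
  A_perm <- snf_fuse(lapply(E_list, function(E) E[perm, perm]), p)
  expect_equal(A_perm, A[perm, perm], tolerance = 1e-12)
})

test_that("single-view fusion degenerates to that view's global kernel", {
  set.seed(9)
  E <- affinity_kernel(matrix(rnorm(5 * 8), 5, 8), snf_params(K = 3))
  expect_message(A <- snf_fuse(list(E), snf_params(K = 3)), "single view")
  P <- global_kernel(E)
  expect_equal(A, (P + t(P)) / 2)
})
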