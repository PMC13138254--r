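test_that("projection-matrix update recovers an interior optimum exactly", {
  set.seed(21)
  # H with orthonormal rows, W0 strictly inside the unit ball: the constraint
  # is inactive and ADMM must solve the least-squares problem
  H <- t(qr.Q(qr(matrix(rnorm(8 * 3), 8, 3))))        # 3 x 8
  W0 <- matrix(rnorm(6 * 3), 6, 3)
  W0 <- sweep(W0, 2, sqrt(colSums(W0^2)) / 0.8, "/")   # column norms 0.8
  X <- W0 %*% H
  res <- update_W(X, H, admm_params(max_inner_iters = 2000, primal_tol = 1e-12))
  expect_lt(norm(res$W - W0, "F"), 1e-6)
  expect_true(res$converged)
})

test_that("projection-matrix update respects the unit ball and the boundary case", {
  set.seed(22)
  X <- matrix(rnorm(10 * 15), 10, 15) * 3
  H <- matrix(rnorm(4 * 15), 4, 15)
  res <- update_W(X, H, admm_params(max_inner_iters = 200))
  expect_true(all(colSums(res$W^2) <= 1 + 1e-8))

  # scalar problem min (2 - w)^2 over |w| <= 1: optimum at the boundary
  res1 <- update_W(matrix(2), matrix(1), admm_params(max_inner_iters = 500, primal_tol = 1e-10))
  expect_equal(res1$W[1, 1], 1, tolerance = 1e-6)

  expect_error(update_W(matrix(NaN), matrix(1)), "non-finite")
})

test_that("warm-started update never worsens the reconstruction subobjective", {
  set.seed(23)
  X <- matrix(rnorm(12 * 20), 12, 20)
  H1 <- matrix(rnorm(5 * 20), 5, 20)
  H2 <- H1 + 0.1 * matrix(rnorm(5 * 20), 5, 20)
  r1 <- update_W(X, H1, admm_params(max_inner_iters = 100))
  before <- norm(X - r1$W %*% H2, "F")^2
  r2 <- update_W(X, H2, admm_params(max_inner_iters = 100), warm_start = r1)
  after <- norm(X - r2$W %*% H2, "F")^2
  expect_lte(after, before + 1e-8)
})

test_that("aggregated coefficients match the expanded reconstruction term", {
  set.seed(24)
  W_list <- lapply(c(7, 5), function(dv) matrix(rnorm(dv * 3), dv, 3))
  X_list <- lapply(c(7, 5), function(dv) matrix(rnorm(dv * 9), dv, 9))
  eq <- assemble_EQ(W_list, X_list)
  expect_equal(eq$E, t(eq$E))
  expect_true(all(eigen(eq$E, symmetric = TRUE, only.values = TRUE)$values > -1e-12))

  # single view with orthonormal columns: E is the identity
  Wo <- qr.Q(qr(matrix(rnorm(7 * 3), 7, 3)))
  expect_equal(assemble_EQ(list(Wo), list(X_list[[1]]))$E, diag(3), tolerance = 1e-12)

  # finite differences of sum_v ||X - W H||_F^2 equal 2 (E H - Q)
  H <- matrix(rnorm(3 * 9), 3, 9)
  f <- function(H) sum(vapply(1:2, function(v) norm(X_list[[v]] - W_list[[v]] %*% H, "F")^2,
                              numeric(1)))
  g_num <- matrix(0, 3, 9)
  h <- 1e-6
  for (i in 1:3) for (j in 1:9) {
    Hp <- H; Hp[i, j] <- Hp[i, j] + h
    Hm <- H; Hm[i, j] <- Hm[i, j] - h
    g_num[i, j] <- (f(Hp) - f(Hm)) / (2 * h)
  }
  expect_equal(g_num, 2 * (eq$E %*% H - eq$Q), tolerance = 1e-5)
})

test_that("latent update solves the Sylvester optimality condition", {
  # scalar case: h = q / (e + beta * l)
  h <- update_H(matrix(2), matrix(6), matrix(1 - 1e-6), beta = 1, eps = 1e-6)
  expect_equal(h[1, 1], 2, tolerance = 1e-9)

  # beta = 0 degenerates to a linear solve
  set.seed(25)
  E <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
  Q <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(update_H(E, Q, diag(6), beta = 0), solve(E, Q))

  # random instance against the Kronecker-vectorized solve
  Z <- matrix(runif(81), 9, 9)
  L <- graph_laplacian(Z)
  beta <- 0.3
  Q2 <- matrix(rnorm(4 * 9), 4, 9)
  H <- update_H(E, Q2, L, beta, eps = 1e-6)
  H_oracle <- oracle_sylvester(E, Q2, L + 1e-6 * diag(9), beta)
  expect_equal(H, H_oracle, tolerance = 1e-6)
  resid <- norm(E %*% H + beta * H %*% (L + 1e-6 * diag(9)) - Q2, "F")
  expect_lt(resid, 1e-8 * max(1, norm(Q2, "F")))
})

test_that("latent update attains the subproblem minimum", {
  set.seed(26)
  E <- crossprod(matrix(rnorm(9), 3, 3)) + 0.5 * diag(3)
  Q <- matrix(rnorm(3 * 7), 3, 7)
  L <- graph_laplacian(matrix(runif(49), 7, 7))
  beta <- 0.4
  obj <- function(H) sum(H * (E %*% H)) - 2 * sum(H * Q) + beta * sum((H %*% (L + 1e-6 * diag(7))) * H)
  H <- update_H(E, Q, L, beta)
  base <- obj(H)
  for (i in 1:100) {
    expect_gte(obj(H + matrix(rnorm(21, sd = 0.1), 3, 7)), base - 1e-10)
  }
})
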