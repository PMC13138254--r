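# Independent brute-force oracles used across tests. These deliberately avoid
# the package's own code paths (loops and scalar arithmetic instead of the
# vectorized production routines).

# Euclidean projection onto the probability simplex by exhaustive support
# enumeration: for every non-empty support S the candidate is
# z_i = c_i + (1 - sum_S c)/|S| on S, 0 elsewhere; the feasible candidate with
# the smallest distance to c is the projection.
oracle_simplex <- function(c) {
  n <- length(c)
  best <- NULL
  best_obj <- Inf
  for (m in 1:n) {
    for (S in utils::combn(n, m, simplify = FALSE)) {
      z <- numeric(n)
      z[S] <- c[S] + (1 - sum(c[S])) / m
      if (all(z >= -1e-12)) {
        obj <- sum((z - c)^2)
        if (obj < best_obj - 1e-15) {
          best_obj <- obj
          best <- pmax(z, 0)
        }
      }
    }
  }
  best
}

# Sylvester solve E H + beta H L = Q via the Kronecker-vectorized linear
# system (I_n x E + beta L^T x I_d) vec(H) = vec(Q).
oracle_sylvester <- function(E, Q, L, beta) {
  d <- nrow(E); n <- ncol(Q)
  M <- kronecker(diag(n), E) + beta * kronecker(t(L), diag(d))
  matrix(solve(M, as.vector(Q)), d, n)
}

# Laplacian quadratic form as an explicit double sum over edges.
oracle_quadform <- function(Z, x) {
  W <- (Z + t(Z)) / 2
  n <- nrow(W)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + W[i, j] * (x[i] - x[j])^2
  s / 2
}

# One fusion round coded entry-by-entry from the update formulas: global and
# local kernels, the cross-view diffusion P(v) <- S(v) Pbar S(v)^T with
# Pbar the average of the other views, per-round symmetrization and
# renormalization to the half-diagonal form, and the final average.
oracle_fuse_one_round <- function(E_list, K) {
  t_v <- length(E_list)
  n <- nrow(E_list[[1]])
  gk <- function(E) {
    P <- matrix(0, n, n)
    for (i in 1:n) {
      off <- 0
      for (k in 1:n) if (k != i) off <- off + E[i, k]
      for (j in 1:n) P[i, j] <- if (i == j) 0.5 else E[i, j] / (2 * off)
    }
    P
  }
  lk <- function(E) {
    S <- matrix(0, n, n)
    for (i in 1:n) {
      sim <- E[i, ]
      others <- setdiff(order(-sim, seq_len(n)), i)
      nb <- c(i, others[seq_len(K)])
      for (j in nb) S[i, j] <- E[i, j] / sum(E[i, nb])
    }
    S
  }
  P_list <- lapply(E_list, gk)
  S_list <- lapply(E_list, lk)
  P_new <- vector("list", t_v)
  for (v in 1:t_v) {
    Pbar <- matrix(0, n, n)
    for (k in 1:t_v) if (k != v) Pbar <- Pbar + P_list[[k]]
    Pbar <- Pbar / (t_v - 1)
    P <- S_list[[v]] %*% Pbar %*% t(S_list[[v]])
    P <- (P + t(P)) / 2
    P_new[[v]] <- gk(P)
  }
  A <- Reduce(`+`, P_new) / t_v
  (A + t(A)) / 2
}

# small clean multi-omics dataset for fast fit tests; the raised signal
# fraction compensates for the reduced feature counts so the subtype
# structure stays clearly recoverable at this scale
tiny_dataset <- function(seed = 1, n = 60, feats = c(150, 120, 90),
                         signal_fraction = 0.15, ...) {
  simulate_multiomics(sim_config(n_samples = n, features_per_view = feats,
                                 n_views = length(feats),
                                 signal_fraction = signal_fraction,
                                 seed = seed, ...))
}

# exact block-diagonal affinity with given block sizes
block_graph <- function(sizes, w = 1) {
  lab <- rep(seq_along(sizes), sizes)
  Z <- outer(lab, lab, "==") * w
  Z
}
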