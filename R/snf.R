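#' Similarity network fusion settings
#'
#' @param mu kernel bandwidth scalar of the scaled exponential kernel.
#' @param K neighborhood size, used both for the kernel's local scale and for
#'   the local (kNN) transition matrix. `NULL` picks
#'   `max(5, min(20, floor(n/10)))` capped at `n - 1` at kernel time.
#' @param n_iterations number of cross-view message-passing rounds.
#' @return An object of class `snf_params`.
#' @export
snf_params <- function(mu = 0.5, K = NULL, n_iterations = 20L) {
  if (mu <= 0) stop("mu must be positive")
  if (!is.null(K) && K < 1) stop("K must be at least 1")
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  structure(list(mu = mu, K = if (is.null(K)) NULL else as.integer(K),
                 n_iterations = as.integer(n_iterations)),
            class = "snf_params")
}

default_K <- function(n) min(max(5L, min(20L, n %/% 10L)), n - 1L)

# Row-ranked neighbor indices by increasing distance (self excluded),
# ties broken toward the smaller sample index.
knn_order <- function(D) {
  n <- nrow(D)
  out <- matrix(0L, n, n - 1L)
  for (i in seq_len(n)) {
    o <- order(D[i, ], seq_len(n))
    out[i, ] <- o[o != i]
  }
  out
}

#' Scaled exponential similarity kernel
#'
#' Computes `e_ij = exp(-rho_ij^2 / (mu * eps_ij))` between sample columns,
#' where `rho` is the Euclidean distance over features and the local scale is
#' `eps_ij = (mean_{k in KNN(i)} rho_ik + mean_{k in KNN(j)} rho_jk + rho_ij) / 3`
#' with K-nearest-neighbor sets excluding the point itself. The diagonal is 1.
#'
#' @param X numeric features x samples matrix (at least 2 samples).
#' @param params an [snf_params()].
#' @return Symmetric n x n similarity matrix with unit diagonal, carrying the
#'   sample IDs as dimnames.
#' @export
affinity_kernel <- function(X, params = snf_params()) {
  stopifnot_finite(X, "view matrix")
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  K <- params$K %||% default_K(n)
  K <- min(K, n - 1L)
  D <- sqrt(col_sqdist(X))
  ord <- knn_order(D)
  mean_knn <- vapply(seq_len(n), function(i) mean(D[i, ord[i, seq_len(K)]]),
                     numeric(1))
  EPS <- (outer(mean_knn, mean_knn, "+") + D) / 3
  EPS <- pmax(EPS, 1e-12)            # duplicate-point guard
  E <- exp(-D^2 / (params$mu * EPS))
  E <- (E + t(E)) / 2                # exact symmetry despite fp noise
  diag(E) <- 1
  dimnames(E) <- list(colnames(X), colnames(X))
  E
}

#' Global (full-graph) transition matrix
#'
#' Normalizes a similarity matrix so that off-diagonal entries of each row
#' carry total mass 1/2 and the diagonal carries 1/2; every row sums to 1.
#'
#' @param E nonnegative similarity matrix with positive off-diagonal mass in
#'   every row.
#' @return Row-stochastic matrix of the same dimension.
#' @export
global_kernel <- function(E) {
  Eoff <- E
  diag(Eoff) <- 0
  off <- rowSums(Eoff)   # summed without the diagonal: the off-diagonal mass
                         # can be tiny relative to e_ii and must not cancel
  if (any(off <= 0)) {
    bad <- which(off <= 0)[1]
    stop(sprintf("sample %s has no off-diagonal similarity (disconnected)",
                 rownames(E)[bad] %||% bad))
  }
  P <- E / (2 * off)
  diag(P) <- 0.5
  P
}

#' Local (kNN-masked) transition matrix
#'
#' Each row is supported on the K most similar other samples plus the sample
#' itself, renormalized to sum 1; all other entries are 0. Ties at the K-th
#' neighbor go to the smaller sample index. The result is generally
#' asymmetric.
#'
#' @param E similarity matrix (larger = closer).
#' @param K neighborhood size, `1 <= K <= n - 1`.
#' @return Row-stochastic sparse-support matrix.
#' @export
local_kernel <- function(E, K) {
  n <- nrow(E)
  if (K < 1 || K > n - 1) stop("K must be in [1, n-1]")
  S <- matrix(0, n, n, dimnames = dimnames(E))
  for (i in seq_len(n)) {
    o <- order(-E[i, ], seq_len(n))
    o <- o[o != i]
    nb <- c(i, o[seq_len(K)])
    S[i, nb] <- E[i, nb] / sum(E[i, nb])
  }
  S
}

#' Fuse per-view similarity networks into a reference graph
#'
#' Runs similarity network fusion: each view's global transition matrix is
#' repeatedly replaced by its local (kNN) diffusion of the average of the
#' other views' matrices, `P(v) <- S(v) %*% mean_{k != v} P(k) %*% t(S(v))`,
#' with all views updated in parallel each round. After every round each
#' `P(v)` is symmetrized and renormalized back to the global-kernel form
#' (off-diagonal row mass 1/2, diagonal 1/2). The fused graph is the average
#' of the final per-view matrices, symmetrized.
#'
#' @param E_list list of per-view similarity matrices over the same samples
#'   (for instance from [affinity_kernel()]).
#' @param params an [snf_params()].
#' @return Symmetric nonnegative fused n x n matrix.
#' @export
snf_fuse <- function(E_list, params = snf_params()) {
  t_views <- length(E_list)
  if (t_views < 1L) stop("need at least one view")
  n <- nrow(E_list[[1]])
  for (E in E_list) {
    if (!all(dim(E) == c(n, n))) stop("all similarity matrices must be n x n over the same samples")
  }
  K <- min(params$K %||% default_K(n), n - 1L)
  P_list <- lapply(E_list, global_kernel)
  if (t_views == 1L) {
    message("single view: fusion skipped, returning its global kernel")
    A <- P_list[[1]]
    return((A + t(A)) / 2)
  }
  S_list <- lapply(E_list, local_kernel, K = K)
  for (it in seq_len(params$n_iterations)) {
    P_new <- vector("list", t_views)
    for (v in seq_len(t_views)) {
      others <- Reduce(`+`, P_list[-v]) / (t_views - 1L)
      P <- S_list[[v]] %*% others %*% t(S_list[[v]])
      P <- (P + t(P)) / 2
      P_new[[v]] <- global_kernel(P)
    }
    P_list <- P_new
  }
  A <- Reduce(`+`, P_list) / t_views
  (A + t(A)) / 2
}
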