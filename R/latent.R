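#' ADMM settings for the projection-matrix update
#'
#' @param rho augmented-Lagrangian penalty (> 0).
#' @param max_inner_iters maximum ADMM iterations per update.
#' @param primal_tol stop when both the primal residual `||W - G||_F` and the
#'   dual residual `rho * ||G - G_prev||_F` fall below this value (the dual
#'   residual guards against premature exit while the proximal term is still
#'   pulling W away from the subproblem optimum).
#' @return An object of class `admm_params`.
#' @export
admm_params <- function(rho = 1.0, max_inner_iters = 50L, primal_tol = 1e-6) {
  if (rho <= 0) stop("rho must be positive")
  if (max_inner_iters < 1) stop("max_inner_iters must be at least 1")
  if (primal_tol < 0) stop("primal_tol must be nonnegative")
  structure(list(rho = rho, max_inner_iters = as.integer(max_inner_iters),
                 primal_tol = primal_tol), class = "admm_params")
}

# Scale columns of V into the unit Euclidean ball: g_j = v_j / max(1, ||v_j||)
project_unit_columns <- function(V) {
  nrm <- sqrt(colSums(V^2))
  scl <- pmax(1, nrm)
  sweep(V, 2L, scl, "/")
}

#' Update one view's projection matrix under unit-norm columns
#'
#' Solves `min_W ||X - W H||_F^2 s.t. ||w_j||_2^2 <= 1` by ADMM with an
#' auxiliary copy G constrained to the unit ball:
#' W-step `W = (X H' + rho (G - T)) (H H' + rho I)^{-1}`, G-step column-wise
#' projection of `W + T` into the unit ball, dual step `T <- T + W - G`.
#' The returned matrix is the feasible copy G at exit, so the constraint
#' holds exactly.
#'
#' @param X_v view matrix, features x samples.
#' @param H latent matrix, d x samples.
#' @param params an [admm_params()].
#' @param warm_start optional list with `W`, `G`, `T` from a previous call
#'   (used across outer iterations for speed).
#' @return List with `W` (feasible solution, = `G`), `G`, `T`, `iterations`,
#'   and `converged`.
#' @export
update_W <- function(X_v, H, params = admm_params(), warm_start = NULL) {
  stopifnot_finite(X_v, "X_v"); stopifnot_finite(H, "H")
  d <- nrow(H)
  dv <- nrow(X_v)
  if (ncol(X_v) != ncol(H)) stop("X_v and H must have the same number of samples")
  rho <- params$rho
  XHt <- tcrossprod(X_v, H)                    # constant across inner iterations
  R <- chol(tcrossprod(H) + rho * diag(d))
  if (is.null(warm_start)) {
    G <- matrix(0, dv, d)
    Tm <- matrix(0, dv, d)
  } else {
    G <- warm_start$G
    Tm <- warm_start$T
  }
  converged <- FALSE
  it <- 0L
  W <- G
  for (it in seq_len(params$max_inner_iters)) {
    G_prev <- G
    W <- t(backsolve(R, backsolve(R, t(XHt + rho * (G - Tm)), transpose = TRUE)))
    G <- project_unit_columns(W + Tm)
    Tm <- Tm + W - G
    if (fnorm(W - G) <= params$primal_tol &&
        rho * fnorm(G - G_prev) <= params$primal_tol) { converged <- TRUE; break }
  }
  list(W = G, G = G, T = Tm, iterations = it, converged = converged)
}

#' Aggregate quadratic and linear coefficients of the latent subproblem
#'
#' With all projection matrices fixed, the reconstruction term
#' `sum_v ||X(v) - W(v) H||_F^2` is `Tr(H' E H) - 2 Tr(H' Q)` up to a
#' constant, with `E = sum_v W(v)' W(v)` and `Q = sum_v W(v)' X(v)`.
#'
#' @param W_list list of per-view projection matrices (features x d).
#' @param X_views list of per-view data matrices (features x samples).
#' @return List with `E` (d x d, symmetric PSD) and `Q` (d x n).
#' @export
assemble_EQ <- function(W_list, X_views) {
  if (length(W_list) != length(X_views)) stop("one W per view required")
  E <- Reduce(`+`, lapply(W_list, crossprod))
  Q <- Reduce(`+`, Map(function(W, X) crossprod(W, X), W_list, X_views))
  E <- (E + t(E)) / 2
  list(E = E, Q = Q)
}

#' Solve the latent-matrix Sylvester equation
#'
#' Returns the stationary point of the latent subproblem, i.e. the solution H
#' of `E H + beta H (L_Z + eps I) = Q`. Both coefficient matrices are
#' symmetric, so the equation is solved exactly by simultaneous
#' eigendecomposition: with `E = U diag(a) U'` and
#' `L_Z + eps I = V diag(b) V'`, the solution is
#' `H = U ((U' Q V) / (a_i + beta b_j)) V'`. The small ridge `eps` keeps the
#' spectra from sharing an exact zero; if a denominator still (numerically)
#' vanishes the solve is retried with `eps` scaled by 10, up to 3 times.
#'
#' @param E symmetric d x d PSD matrix.
#' @param Q d x n matrix.
#' @param L_Z symmetric n x n graph Laplacian.
#' @param beta graph-regularization weight (>= 0).
#' @param eps stabilization ridge added to `L_Z` (> 0).
#' @return d x n matrix `H`.
#' @export
update_H <- function(E, Q, L_Z, beta, eps = 1e-6) {
  stopifnot_finite(E, "E"); stopifnot_finite(Q, "Q"); stopifnot_finite(L_Z, "L_Z")
  if (beta < 0) stop("beta must be nonnegative")
  if (eps <= 0) stop("eps must be positive")
  if (beta == 0) return(solve(E, Q))
  ee <- eigen(E, symmetric = TRUE)
  for (attempt in 0:3) {
    eps_a <- eps * 10^attempt
    el <- eigen(L_Z + eps_a * diag(nrow(L_Z)), symmetric = TRUE)
    denom <- outer(ee$values, beta * el$values, "+")
    if (all(abs(denom) > 1e-14)) {
      Ct <- (crossprod(ee$vectors, Q) %*% el$vectors) / denom
      H <- ee$vectors %*% tcrossprod(Ct, el$vectors)
      res <- fnorm(E %*% H + beta * H %*% (L_Z + eps_a * diag(nrow(L_Z))) - Q)
      if (res <= 1e-8 * max(1, fnorm(Q))) return(H)
    }
  }
  stop("Sylvester solve failed: shared (near-)zero eigenvalues persist after eps escalation")
}
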