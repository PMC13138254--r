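#' Graph Laplacian of a (possibly asymmetric) similarity matrix
#'
#' Builds `L = D - (Z + Z') / 2` with degrees `d_ii = sum_j (z_ij + z_ji) / 2`.
#' For nonnegative `Z` the result is symmetric positive semidefinite with zero
#' row sums.
#'
#' @param Z nonnegative n x n matrix.
#' @return Symmetric n x n Laplacian.
#' @export
graph_laplacian <- function(Z) {
  W <- (Z + t(Z)) / 2
  diag(rowSums(W)) - W
}

#' Euclidean projection onto the probability simplex
#'
#' Returns the nearest point (in Euclidean norm) to `c` in
#' `{z : z >= 0, sum(z) = 1}` using the sort-and-threshold rule: the shift
#' `eta` is chosen so that `sum(pmax(c + eta, 0)) = 1`. The implied upper
#' bound `z <= 1` follows from nonnegativity and the sum constraint.
#'
#' @param c finite numeric vector.
#' @return Vector on the simplex, same length as `c`.
#' @export
project_simplex <- function(c) {
  stopifnot_finite(c, "c")
  u <- sort(c, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u + (1 - css) / j > 0])
  eta <- (1 - css[rho]) / rho
  pmax(c + eta, 0)
}

#' Update the learned similarity graph
#'
#' Minimizes, row by row, `alpha * ||z_i - a_i||^2 + sum_j d_ij z_ij` over the
#' probability simplex, where `d_ij = beta * ||h_i - h_j||_2^2` is the squared
#' latent distance between samples. Completing the square gives the row
#' target `c_ij = a_ij - d_ij / (2 alpha)`, so each row is the simplex
#' projection of its target and the rows are independent.
#'
#' @param A reference (fused) similarity matrix, n x n.
#' @param H latent matrix, d x n (samples in columns).
#' @param alpha weight keeping Z close to A (> 0).
#' @param beta weight of the latent-distance penalty (>= 0).
#' @return n x n matrix with every row on the probability simplex.
#' @export
update_Z <- function(A, H, alpha, beta) {
  if (alpha <= 0) stop("alpha must be positive")
  if (beta < 0) stop("beta must be nonnegative")
  n <- nrow(A)
  if (ncol(H) != n) stop("H must have one column per sample")
  D2 <- col_sqdist(H)
  C <- A - (beta * D2) / (2 * alpha)
  Z <- t(apply(C, 1L, project_simplex))
  dimnames(Z) <- dimnames(A)
  Z
}
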