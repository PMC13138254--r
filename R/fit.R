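#' Optimizer settings for unified latent and similarity learning
#'
#' @param alpha0 scale of the graph-fidelity weight; the effective
#'   `alpha = alpha0 * sum_v d(v) / n` adapts to the feature-to-sample ratio.
#'   Values in `[2, 3]` work well.
#' @param alpha optional explicit override of the effective weight.
#' @param beta graph-regularization weight coupling the latent distances to
#'   the learned graph; fixed at 0.1 by default.
#' @param d latent dimension; typically searched in `[20, 120]`.
#' @param snf an [snf_params()] for building the fused reference graph.
#' @param admm an [admm_params()] for the projection-matrix updates.
#' @param outer_tol relative objective-change convergence tolerance.
#' @param max_outer_iters cap on alternating sweeps.
#' @param eps Sylvester stabilization ridge.
#' @param standardize z-score each feature within each view before fitting.
#' @param init `"random"` (scaled standard normal, seeded) or `"pca"`
#'   (principal components of the concatenated standardized views).
#' @param seed integer seed controlling initialization (and nothing else).
#' @return An object of class `ulsl_params`.
#' @export
ulsl_params <- function(alpha0 = 2.5, alpha = NULL, beta = 0.1, d = 60L,
                        snf = snf_params(), admm = admm_params(),
                        outer_tol = 1e-5, max_outer_iters = 100L,
                        eps = 1e-6, standardize = TRUE,
                        init = c("random", "pca"), seed = 1L) {
  if (is.null(alpha) && alpha0 <= 0) stop("alpha0 must be positive")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  if (beta < 0) stop("beta must be nonnegative")
  if (d < 1) stop("d must be at least 1")
  if (max_outer_iters < 1) stop("max_outer_iters must be at least 1")
  structure(list(alpha0 = alpha0, alpha = alpha, beta = beta, d = as.integer(d),
                 snf = snf, admm = admm, outer_tol = outer_tol,
                 max_outer_iters = as.integer(max_outer_iters), eps = eps,
                 standardize = isTRUE(standardize), init = match.arg(init),
                 seed = as.integer(seed)),
            class = "ulsl_params")
}

#' Effective graph-fidelity weight from the feature-to-sample ratio
#'
#' `alpha = alpha0 * sum(view_dims) / n`: datasets with many features relative
#' to samples anchor the learned graph more strongly to the fused reference,
#' balancing the reconstruction term that grows with total feature count.
#'
#' @param alpha0 positive scale factor.
#' @param view_dims integer vector of per-view feature counts.
#' @param n number of samples (>= 1).
#' @return Scalar weight.
#' @export
alpha_from_ratio <- function(alpha0, view_dims, n) {
  if (alpha0 <= 0) stop("alpha0 must be positive")
  if (any(view_dims <= 0)) stop("view dimensions must be positive")
  if (n < 1) stop("n must be at least 1")
  alpha0 * sum(view_dims) / n
}

#' Unified objective value
#'
#' `sum_v ||X(v) - W(v) H||_F^2 + alpha ||Z - A||_F^2 + beta Tr(H L_Z H')`.
#' Each term is nonnegative (the Laplacian of a nonnegative graph is PSD).
#'
#' @param X_views list of view matrices.
#' @param W_list list of projection matrices.
#' @param H latent matrix.
#' @param Z learned graph.
#' @param A fused reference graph.
#' @param alpha,beta objective weights.
#' @return Scalar objective value.
#' @export
ulsl_objective <- function(X_views, W_list, H, Z, A, alpha, beta) {
  recon <- sum(vapply(seq_along(X_views),
                      function(v) fnorm(X_views[[v]] - W_list[[v]] %*% H)^2,
                      numeric(1)))
  graph_fit <- alpha * fnorm(Z - A)^2
  smooth <- beta * sum((H %*% graph_laplacian(Z)) * H)
  recon + graph_fit + smooth
}

# z-score each feature, then scale the view by 1/sqrt(d_v) so every sample's
# per-view profile has unit expected norm; this keeps the latent coordinates
# O(1) across views of very different dimensionality, which the
# feature-to-sample calibration of alpha assumes
standardize_views <- function(X_views) {
  lapply(X_views, function(X) {
    mu <- rowMeans(X)
    sdv <- apply(X, 1L, stats::sd)
    ((X - mu) / sdv) / sqrt(nrow(X))
  })
}

check_views <- function(X_views, sample_ids) {
  for (v in seq_along(X_views)) {
    X <- X_views[[v]]
    if (ncol(X) != length(sample_ids))
      stop(sprintf("view %d is not aligned with the sample set", v))
    stopifnot_finite(X, sprintf("view %d", v))
    sdv <- apply(X, 1L, stats::sd)
    if (any(sdv == 0)) {
      bad <- which(sdv == 0)
      stop(sprintf("view %d has zero-variance feature(s): %s", v,
                   paste(utils::head(rownames(X)[bad] %||% bad, 5), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Fit the unified latent and similarity model
#'
#' Runs the alternating optimizer: (i) optionally z-score features per view;
#' (ii) build per-view similarity kernels and fuse them into the reference
#' graph A (held fixed thereafter); (iii) initialize the projection matrices
#' and latent matrix from the seed, and the learned graph Z as the row-wise
#' simplex projection of A; (iv) sweep W (ADMM per view, warm-started), H
#' (Sylvester solve), Z (row simplex projections), recording the unified
#' objective after each sweep; (v) stop when the relative objective change
#' drops below `outer_tol` or `max_outer_iters` is reached.
#'
#' @param dataset a [multi_omics()] object (or a bare list of view matrices).
#' @param params a [ulsl_params()].
#' @param verbose log the objective value after every sweep.
#' @return An object of class `ulsl_fit`: list with `Z`, `H`, `W_list`, `A`,
#'   `objective_trace`, `n_iterations`, `converged`, `alpha`,
#'   `diagnostics` (per-sweep feasibility measures), `params`, `sample_ids`.
#' @examples
#' d <- simulate_multiomics(sim_config(n_samples = 60, features_per_view = c(80, 60, 40)))
#' fit <- ulsl_fit(d, ulsl_params(d = 10, max_outer_iters = 30))
#' plot(fit$objective_trace, type = "b", ylab = "objective")
#' @export
ulsl_fit <- function(dataset, params = ulsl_params(), verbose = FALSE) {
  if (!inherits(dataset, "multi_omics")) dataset <- multi_omics(dataset)
  X_views <- dataset$views
  sample_ids <- dataset$sample_ids
  n <- length(sample_ids)
  check_views(X_views, sample_ids)
  if (length(X_views) < 2L)
    warning("fitting with a single view: fusion degenerates to that view's kernel")
  if (params$standardize) X_views <- standardize_views(X_views)

  E_list <- lapply(X_views, affinity_kernel, params = params$snf)
  A <- snf_fuse(E_list, params$snf)
  alpha <- params$alpha %||%
    alpha_from_ratio(params$alpha0, vapply(X_views, nrow, integer(1)), n)
  beta <- params$beta
  d <- params$d

  init <- with_seed(params$seed, {
    if (params$init == "pca") {
      Xc <- do.call(rbind, X_views)
      sv <- svd(Xc, nu = 0, nv = d)
      H0 <- t(sv$v) * sv$d[seq_len(d)] / sqrt(d)
      list(H = H0,
           W = lapply(X_views, function(X) matrix(stats::rnorm(nrow(X) * d), ncol = d) / sqrt(d)))
    } else {
      list(H = matrix(stats::rnorm(d * n), d, n) / sqrt(d),
           W = lapply(X_views, function(X) matrix(stats::rnorm(nrow(X) * d), ncol = d) / sqrt(d)))
    }
  })
  H <- init$H
  W_state <- lapply(init$W, function(W0) list(G = project_unit_columns(W0),
                                              T = matrix(0, nrow(W0), ncol(W0))))
  Z <- t(apply(A, 1L, project_simplex))

  trace <- numeric(0)
  diag_w <- diag_z <- numeric(0)
  converged <- FALSE
  prev <- Inf
  for (r in seq_len(params$max_outer_iters)) {
    for (v in seq_along(X_views)) {
      W_state[[v]] <- update_W(X_views[[v]], H, params$admm, warm_start = W_state[[v]])
    }
    W_list <- lapply(W_state, `[[`, "W")
    eq <- assemble_EQ(W_list, X_views)
    H <- update_H(eq$E, eq$Q, graph_laplacian(Z), beta, params$eps)
    Z <- update_Z(A, H, alpha, beta)
    obj <- ulsl_objective(X_views, W_list, H, Z, A, alpha, beta)
    trace <- c(trace, obj)
    if (verbose) message(sprintf("sweep %3d: objective %.8g", r, obj))
    diag_w <- c(diag_w, max(vapply(W_list, function(W) max(colSums(W^2)), numeric(1))))
    diag_z <- c(diag_z, max(abs(rowSums(Z) - 1)))
    if (is.finite(prev) && abs(obj - prev) / max(1, prev) < params$outer_tol) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  structure(
    list(Z = Z, H = H, W_list = lapply(W_state, `[[`, "W"), A = A,
         objective_trace = trace, n_iterations = length(trace),
         converged = converged, alpha = alpha,
         diagnostics = list(max_W_colnorm_sq = diag_w,
                            max_Z_rowsum_dev = diag_z),
         params = params, sample_ids = sample_ids),
    class = "ulsl_fit")
}

#' @export
print.ulsl_fit <- function(x, ...) {
  cat(sprintf("ulsl fit: %d samples, %d views, d = %d\n",
              length(x$sample_ids), length(x$W_list), nrow(x$H)))
  cat(sprintf("  alpha = %.4g, beta = %.4g\n", x$alpha, x$params$beta))
  cat(sprintf("  %d sweeps, converged = %s, final objective = %.6g\n",
              x$n_iterations, x$converged, utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Grid search over the weight scale and latent dimension
#'
#' Re-runs [ulsl_fit()] for every combination of `alpha0` and `d` and scores
#' each fit with a caller-supplied criterion (e.g. NMI against known labels,
#' or the eigengap magnitude of the learned graph when no labels exist).
#'
#' @param dataset a [multi_omics()] object.
#' @param alpha0_values,d_values numeric vectors of candidate values.
#' @param params base [ulsl_params()]; `alpha0` and `d` are overridden.
#' @param criterion function `(fit) -> scalar` (larger = better).
#' @return `data.frame` with columns `alpha0`, `d`, `score`, `converged`.
#' @export
ulsl_grid <- function(dataset, alpha0_values, d_values, params = ulsl_params(),
                      criterion) {
  grid <- expand.grid(alpha0 = alpha0_values, d = d_values)
  grid$score <- NA_real_
  grid$converged <- NA
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$alpha0 <- grid$alpha0[i]
    p$d <- as.integer(grid$d[i])
    fit <- ulsl_fit(dataset, p)
    grid$score[i] <- criterion(fit)
    grid$converged[i] <- fit$converged
  }
  grid
}
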