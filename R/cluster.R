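#' Spectral clustering of a learned similarity graph
#'
#' Symmetrizes the graph, forms the normalized Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}`, embeds the samples with the eigenvectors of
#' the k smallest eigenvalues, row-normalizes the embedding and partitions it
#' with seeded k-means (multiple restarts).
#'
#' @param Z n x n nonnegative similarity matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return List of class `spectral_clustering` with `labels` (integers
#'   `1..k`), `k`, `embedding` (n x k, row-normalized), and `eigenvalues`
#'   (full ascending Laplacian spectrum).
#' @export
spectral_cluster <- function(Z, k, seed = 1L, nstart = 10L) {
  if (k < 2) stop("k must be at least 2")
  n <- nrow(Z)
  sp <- laplacian_spectrum(Z)
  n_comp <- sum(sp$values < 1e-10)
  if (n_comp > k)
    warning(sprintf("graph has %d connected components but k = %d", n_comp, k))
  U <- sp$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- with_seed(seed, stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100L))
  structure(list(labels = as.integer(km$cluster), k = as.integer(k),
                 embedding = U, eigenvalues = sp$values,
                 sample_ids = rownames(Z)),
            class = "spectral_clustering")
}

# ascending eigensystem of the symmetric normalized Laplacian of (Z+Z')/2
laplacian_spectrum <- function(Z) {
  W <- (Z + t(Z)) / 2
  deg <- rowSums(W)
  if (any(deg <= 0)) stop("graph has isolated sample(s) with zero degree")
  dh <- 1 / sqrt(deg)
  Lsym <- diag(nrow(W)) - (dh * W) * rep(dh, each = nrow(W))
  Lsym <- (Lsym + t(Lsym)) / 2
  e <- eigen(Lsym, symmetric = TRUE)
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE])
}

#' Choose the cluster number by the eigengap heuristic
#'
#' Returns the k in `[k_min, k_max]` maximizing the gap between consecutive
#' ascending eigenvalues of the normalized Laplacian,
#' `lambda_{k+1} - lambda_k`; ties go to the smaller k.
#'
#' @param Z similarity matrix.
#' @param k_min,k_max search range, `2 <= k_min <= k_max <= n - 1`.
#' @return Integer cluster number.
#' @export
eigengap_k <- function(Z, k_min = 2L, k_max = 8L) {
  n <- nrow(Z)
  if (!(2 <= k_min && k_min <= k_max && k_max <= n - 1))
    stop("need 2 <= k_min <= k_max <= n - 1")
  lam <- laplacian_spectrum(Z)$values
  ks <- seq.int(k_min, k_max)
  gaps <- lam[ks + 1L] - lam[ks]
  ks[which.max(gaps)]
}

#' Cluster-number search range from the sample size
#'
#' Piecewise rule: n > 500 gives `(4, 8)`; 200 <= n <= 500 gives `(3, 6)`;
#' n < 200 gives `(2, 5)`.
#'
#' @param n sample size.
#' @return Integer vector `c(k1, k2)`.
#' @export
k_search_range <- function(n) {
  if (n > 500) c(4L, 8L) else if (n >= 200) c(3L, 6L) else c(2L, 5L)
}

#' Choose the cluster number by the gap statistic
#'
#' Computes, for each k in the search window, the pooled log within-cluster
#' dispersion `log W_k` of k-means on the embedding and compares it with `B`
#' reference draws uniform over the embedding's bounding box:
#' `Gap(k) = mean_b log W*_kb - log W_k`. Returns the smallest k in
#' `[k1, k2]` with `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error
#' rule); if no k qualifies, the k maximizing the gap.
#'
#' @param embedding n x m numeric matrix (e.g. a spectral embedding).
#' @param k1,k2 search range.
#' @param B number of reference draws.
#' @param seed integer seed (reference draws and k-means restarts).
#' @return Integer cluster number.
#' @export
gap_statistic_k <- function(embedding, k1, k2, B = 10L, seed = 1L) {
  if (k1 > k2) stop("k1 must be <= k2")
  if (B < 1) stop("B must be at least 1")
  if (k1 == k2) return(as.integer(k1))
  n <- nrow(embedding)
  ks <- seq.int(k1, min(k2 + 1L, n - 1L))
  wk <- function(X, k) stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L)$tot.withinss
  lo <- apply(embedding, 2L, min)
  hi <- apply(embedding, 2L, max)
  with_seed(seed, {
    logW <- vapply(ks, function(k) log(wk(embedding, k)), numeric(1))
    logWstar <- matrix(NA_real_, B, length(ks))
    for (b in seq_len(B)) {
      ref <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      logWstar[b, ] <- vapply(ks, function(k) log(wk(ref, k)), numeric(1))
    }
    gap <- colMeans(logWstar) - logW
    s <- apply(logWstar, 2L, stats::sd) * sqrt(1 + 1 / B)
    in_win <- which(ks >= k1 & ks <= k2)
    for (i in in_win) {
      if (i + 1L <= length(ks) && gap[i] >= gap[i + 1L] - s[i + 1L])
        return(as.integer(ks[i]))
    }
    as.integer(ks[in_win][which.max(gap[in_win])])
  })
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table divided by the geometric
#' mean of the two label entropies (configurable to the arithmetic-mean or
#' max variants). Equals 1 for identical partitions up to relabeling and 0
#' for independent ones. When either partition has zero entropy (a single
#' cluster), the value is 1 if the partitions are identical and 0 otherwise.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @param variant normalization: `"sqrt"` (geometric mean, default),
#'   `"mean"`, or `"max"`.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b, variant = c("sqrt", "mean", "max")) {
  variant <- match.arg(variant)
  if (length(labels_a) != length(labels_b)) stop("label vectors must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hb <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (ha == 0 || hb == 0) {
    same <- nmi_identical(labels_a, labels_b)
    return(if (same) 1 else 0)
  }
  p <- tab / n
  e <- outer(pj, pk)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / e[nz]))
  denom <- switch(variant, sqrt = sqrt(ha * hb), mean = (ha + hb) / 2,
                  max = max(ha, hb))
  min(max(mi / denom, 0), 1)
}

# identical partitions up to relabeling: contingency table has exactly one
# positive cell per row and per column
nmi_identical <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
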