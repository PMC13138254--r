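#' Simulation configuration for synthetic multi-omics data
#'
#' Describes a block-mean Gaussian multi-omics design in which each view can
#' distinguish only a subset of the subtypes: one pair of subtypes is assigned
#' identical means in every view, with the merged pair varying across views so
#' that integration of all views separates every subtype.
#'
#' @param n_samples total number of samples across all subtypes.
#' @param n_clusters number of subtypes (at least 3: each view merges one pair
#'   and must still show at least two groups).
#' @param n_views number of omics views (at least 2).
#' @param features_per_view integer vector of length `n_views`, features per view.
#' @param signal_fraction proportion of features per view carrying
#'   subtype-specific mean shifts (the "differential" features).
#' @param noise `"low"` or `"high"`, mapped to `noise_sd` 1 and 2 respectively;
#'   ignored when `noise_sd` is supplied.
#' @param noise_sd optional explicit Gaussian noise standard deviation.
#' @param regime `"clear"` or `"ambiguous"`: preset subtype-boundary
#'   sharpness, mapped to `boundary_clarity` 2.5 and 0.8 respectively;
#'   ignored when `boundary_clarity` is supplied. The clear regime is
#'   calibrated so that integrative clustering recovers all subtypes exactly;
#'   in the ambiguous regime performance degrades without collapsing to
#'   chance.
#' @param boundary_clarity optional explicit effect-size scalar: spacing
#'   between adjacent subtype means on differential features, in units of the
#'   noise standard deviation at the low-noise setting.
#' @param cluster_sizes optional integer vector of subtype sizes summing to
#'   `n_samples`; defaults to equal sizes.
#' @param merged_pairs optional list (length `n_views`) of integer pairs: the
#'   two subtypes that share a mean in each view. Defaults to
#'   [design_view_confusability()].
#' @param seed integer seed; the generated dataset is a deterministic
#'   function of the configuration.
#' @return An object of class `sim_config`.
#' @seealso [simulate_multiomics()]
#' @export
sim_config <- function(n_samples = 400L, n_clusters = 4L, n_views = 3L,
                       features_per_view = c(1000L, 500L, 300L),
                       signal_fraction = 0.05,
                       noise = c("low", "high"), noise_sd = NULL,
                       regime = c("clear", "ambiguous"),
                       boundary_clarity = NULL,
                       cluster_sizes = NULL, merged_pairs = NULL,
                       seed = 1L) {
  n_samples  <- as.integer(n_samples)
  n_clusters <- as.integer(n_clusters)
  n_views    <- as.integer(n_views)
  if (n_clusters < 2L) stop("n_clusters must be at least 2")
  if (n_views < 2L) stop("n_views must be at least 2")
  if (length(features_per_view) == 1L)
    features_per_view <- rep(features_per_view, n_views)
  if (length(features_per_view) != n_views)
    stop("features_per_view must have one entry per view")
  if (!(signal_fraction > 0 && signal_fraction <= 1))
    stop("signal_fraction must be in (0, 1]")
  if (is.null(noise_sd)) {
    noise <- match.arg(noise)
    noise_sd <- c(low = 1.0, high = 2.0)[[noise]]
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(boundary_clarity)) {
    regime <- match.arg(regime)
    boundary_clarity <- c(clear = 2.5, ambiguous = 0.8)[[regime]]
  }
  if (boundary_clarity <= 0) stop("boundary_clarity must be positive")
  if (is.null(cluster_sizes)) {
    if (n_samples %% n_clusters != 0L)
      stop("n_samples must be divisible by n_clusters when cluster_sizes is not given")
    cluster_sizes <- rep(n_samples %/% n_clusters, n_clusters)
  }
  cluster_sizes <- as.integer(cluster_sizes)
  if (length(cluster_sizes) != n_clusters || any(cluster_sizes < 1L) ||
      sum(cluster_sizes) != n_samples)
    stop("cluster_sizes must be positive and sum to n_samples")
  if (is.null(merged_pairs)) {
    merged_pairs <- design_view_confusability(n_clusters, n_views)
  } else {
    validate_confusability(merged_pairs, n_clusters, n_views)
  }
  structure(
    list(n_samples = n_samples, n_clusters = n_clusters, n_views = n_views,
         features_per_view = as.integer(features_per_view),
         signal_fraction = signal_fraction, noise_sd = noise_sd,
         boundary_clarity = boundary_clarity, cluster_sizes = cluster_sizes,
         merged_pairs = merged_pairs, seed = as.integer(seed)),
    class = "sim_config")
}

#' Assign one indistinguishable subtype pair to each view
#'
#' Chooses, for every view, an unordered pair of subtypes that will share a
#' mean vector in that view. Pairs are taken in lexicographic order and cycled
#' if there are more views than distinct pairs. No pair is merged in every
#' view, so joint use of all views can separate all subtypes.
#'
#' @param n_clusters number of subtypes (at least 3).
#' @param n_views number of views.
#' @return List of length `n_views`; each element an integer vector of two
#'   subtype indices.
#' @export
design_view_confusability <- function(n_clusters, n_views) {
  n_clusters <- as.integer(n_clusters)
  n_views <- as.integer(n_views)
  if (n_clusters < 3L)
    stop("n_clusters must be at least 3: merging a pair must leave >= 2 groups per view")
  all_pairs <- utils::combn(n_clusters, 2L, simplify = FALSE)
  pairs <- all_pairs[((seq_len(n_views) - 1L) %% length(all_pairs)) + 1L]
  validate_confusability(pairs, n_clusters, n_views)
  pairs
}

#' Validate a per-view merged-pair assignment
#'
#' Checks that each pair is a valid subtype pair and that no single pair is
#' merged in every view (which would make those two subtypes unrecoverable
#' even after integration).
#'
#' @param pairs list of integer pairs, one per view.
#' @param n_clusters,n_views design dimensions.
#' @return `pairs`, invisibly; errors when invalid.
#' @export
validate_confusability <- function(pairs, n_clusters, n_views) {
  if (length(pairs) != n_views) stop("need one merged pair per view")
  if (n_clusters < 3L) stop("n_clusters must be at least 3")
  keys <- vapply(pairs, function(p) {
    p <- sort(as.integer(p))
    if (length(p) != 2L || p[1] == p[2] || p[1] < 1L || p[2] > n_clusters)
      stop("each merged pair must name two distinct subtypes in 1..n_clusters")
    paste(p, collapse = "-")
  }, character(1))
  if (length(unique(keys)) == 1L && n_views >= 1L)
    stop(sprintf("subtype pair {%s} is merged in every view; these subtypes would be inseparable",
                 gsub("-", ",", keys[1])))
  invisible(pairs)
}

#' Generate a synthetic multi-omics dataset
#'
#' Draws each view as a block-mean signal matrix plus i.i.d. Gaussian noise.
#' Within a view, a `signal_fraction` of the features carry subtype-specific
#' mean shifts: the view's merged subtype pair shares one mean, and the
#' remaining effective groups receive evenly spaced shifts (spacing
#' `boundary_clarity`) in a per-feature random order. All other features are
#' pure noise. The output is a deterministic function of the configuration,
#' including its seed.
#'
#' @param config a [sim_config()].
#' @return An object of class `multi_omics`, a list with `views` (list of
#'   features x samples matrices with sample-ID column names), `sample_ids`,
#'   `true_labels` (integers `1..n_clusters`), and the `config` used.
#' @examples
#' d <- simulate_multiomics(sim_config(n_samples = 40, features_per_view = c(60, 40, 30)))
#' sapply(d$views, dim)
#' table(d$true_labels)
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_clusters
  n <- config$n_samples
  labels <- rep(seq_len(k), config$cluster_sizes)
  sample_ids <- sprintf("S%03d", seq_len(n))
  with_seed(config$seed, {
    views <- vector("list", config$n_views)
    for (v in seq_len(config$n_views)) {
      d_v <- config$features_per_view[v]
      pair <- sort(config$merged_pairs[[v]])
      # collapse the merged pair: effective group index per sample
      grp <- labels
      grp[grp == pair[2]] <- pair[1]
      grp <- match(grp, sort(unique(grp)))     # 1..(k-1)
      n_grp <- k - 1L
      n_sig <- max(1L, round(config$signal_fraction * d_v))
      sig_idx <- sort(sample.int(d_v, n_sig))
      # per-feature group means: evenly spaced shifts in random group order
      shifts <- config$boundary_clarity * (seq_len(n_grp) - (n_grp + 1) / 2)
      M <- matrix(0, nrow = d_v, ncol = n_grp)
      for (f in seq_len(n_sig)) M[sig_idx[f], ] <- shifts[sample.int(n_grp)]
      X <- M[, grp, drop = FALSE] +
        matrix(stats::rnorm(d_v * n, sd = config$noise_sd), d_v, n)
      dimnames(X) <- list(sprintf("V%d_F%04d", v, seq_len(d_v)), sample_ids)
      views[[v]] <- X
    }
    names(views) <- sprintf("view%d", seq_len(config$n_views))
    multi_omics(views, sample_ids, true_labels = labels, config = config)
  })
}

#' Construct a multi-omics dataset container
#'
#' @param views list of features x samples numeric matrices over the same
#'   samples in the same order.
#' @param sample_ids character vector of sample identifiers.
#' @param true_labels optional integer labels (one per sample).
#' @param config optional generating [sim_config()].
#' @return An object of class `multi_omics`.
#' @export
multi_omics <- function(views, sample_ids = NULL, true_labels = NULL, config = NULL) {
  if (!is.list(views) || length(views) < 1L) stop("views must be a non-empty list")
  ns <- vapply(views, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all views must have the same number of samples (columns)")
  if (is.null(sample_ids)) sample_ids <- colnames(views[[1]])
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(ns[1]))
  for (v in seq_along(views)) {
    cn <- colnames(views[[v]])
    if (!is.null(cn) && !identical(cn, sample_ids))
      stop(sprintf("view %d sample order differs from sample_ids", v))
    stopifnot_finite(views[[v]], sprintf("view %d", v))
  }
  if (!is.null(true_labels) && length(true_labels) != ns[1])
    stop("true_labels must have one entry per sample")
  structure(list(views = views, sample_ids = sample_ids,
                 true_labels = true_labels, config = config),
            class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf("multi_omics dataset: %d views, %d samples\n",
              length(x$views), length(x$sample_ids)))
  for (v in seq_along(x$views))
    cat(sprintf("  %s: %d features\n", names(x$views)[v] %||% paste0("view", v),
                nrow(x$views[[v]])))
  if (!is.null(x$true_labels))
    cat("  true labels:", paste(table(x$true_labels), collapse = "/"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
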