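test_that("view confusability design merges a different pair in each view", {
  pairs <- design_view_confusability(4, 3)
  expect_length(pairs, 3)
  keys <- vapply(pairs, function(p) paste(sort(p), collapse = "-"), character(1))
  expect_equal(length(unique(keys)), 3)        # no pair merged in every view
  for (p in pairs) {
    expect_length(p, 2)
    expect_true(all(p %in% 1:4) && p[1] != p[2])
  }

  expect_length(design_view_confusability(3, 2), 2)
  # more views than distinct pairs: cycling is allowed
  expect_length(design_view_confusability(3, 5), 5)

  expect_error(design_view_confusability(2, 3), "at least 3")
  # a pair merged in every view leaves those subtypes unrecoverable
  expect_error(validate_confusability(list(c(1, 2), c(1, 2), c(1, 2)), 4, 3),
               "every view")
})

test_that("generation is deterministic and partitions samples as configured", {
  cfg <- sim_config(n_samples = 48, n_clusters = 4, features_per_view = c(30, 20, 15),
                    seed = 11)
  d1 <- simulate_multiomics(cfg)
  d2 <- simulate_multiomics(cfg)
  expect_identical(d1$views, d2$views)
  expect_identical(d1$true_labels, d2$true_labels)

  expect_equal(as.integer(table(d1$true_labels)), rep(12L, 4))
  for (v in seq_along(d1$views)) {
    expect_true(all(is.finite(d1$views[[v]])))
    expect_true(all(apply(d1$views[[v]], 1, stats::sd) > 0))
    expect_identical(colnames(d1$views[[v]]), d1$sample_ids)
  }

  d3 <- simulate_multiomics(sim_config(n_samples = 48, n_clusters = 4,
                                       features_per_view = c(30, 20, 15), seed = 12))
  expect_false(identical(d1$views[[1]], d3$views[[1]]))
})

test_that("cluster size overrides are validated", {
  cfg <- sim_config(n_samples = 40, n_clusters = 4, features_per_view = c(20, 15),
                    n_views = 2, cluster_sizes = c(5, 10, 10, 15))
  d <- simulate_multiomics(cfg)
  expect_equal(as.integer(table(d$true_labels)), c(5L, 10L, 10L, 15L))
  expect_error(sim_config(n_samples = 40, n_clusters = 4, n_views = 2,
                          features_per_view = c(20, 15),
                          cluster_sizes = c(10, 10, 10, 15)),
               "sum to n_samples")
  expect_error(sim_config(n_samples = 41, n_clusters = 4, n_views = 2,
                          features_per_view = c(20, 15)), "divisible")
})

test_that("each clear-regime view separates exactly its three merged groups", {
  cfg <- sim_config(n_samples = 120, features_per_view = c(300, 200, 150), seed = 3)
  d <- simulate_multiomics(cfg)
  lab <- d$true_labels
  for (v in seq_along(d$views)) {
    X <- scale(t(d$views[[v]]))
    pair <- d$config$merged_pairs[[v]]
    merged <- lab
    merged[merged == pair[2]] <- pair[1]
    set.seed(1)
    km3 <- stats::kmeans(X, 3, nstart = 20)$cluster
    km4 <- stats::kmeans(X, 4, nstart = 20)$cluster
    expect_gt(nmi(km3, merged), 0.95)   # the 3 distinguishable groups
    expect_lt(nmi(km4, lab), 0.95)      # the merged pair cannot be split
  }
})

test_that("separability responds monotonically to noise and signal strength", {
  skip_if_not_installed("cluster")
  sep <- function(signal_fraction, noise_sd, seed) {
    d <- simulate_multiomics(sim_config(
      n_samples = 60, features_per_view = c(60, 50, 40),
      signal_fraction = signal_fraction, noise_sd = noise_sd, seed = seed))
    mean(vapply(d$views, function(X) {
      sil <- cluster::silhouette(d$true_labels, stats::dist(t(X)))
      mean(sil[, "sil_width"])
    }, numeric(1)))
  }
  seeds <- 1:20
  low_noise  <- vapply(seeds, function(s) sep(0.10, 1.0, s), numeric(1))
  high_noise <- vapply(seeds, function(s) sep(0.10, 2.0, s), numeric(1))
  weak_sig   <- vapply(seeds, function(s) sep(0.05, 1.0, s), numeric(1))
  expect_gt(mean(low_noise), mean(high_noise))  # more noise, less separable
  expect_gt(mean(low_noise), mean(weak_sig))    # more signal, more separable
})
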