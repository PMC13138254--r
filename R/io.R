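#' Read a delimited view matrix
#'
#' Expects a delimited text file with sample IDs in the header row, feature
#' IDs in the first column and a numeric body (features x samples).
#' Zero-variance features are dropped with a message, matching the usual
#' preprocessing of omics matrices before similarity construction.
#'
#' @param path file path (TSV/CSV; the separator is auto-detected).
#' @param drop_zero_variance drop constant features (default `TRUE`).
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_view_matrix <- function(path, drop_zero_variance = TRUE) {
  if (!file.exists(path)) stop(sprintf("view file not found: %s", path))
  hdr <- strsplit(readLines(path, n = 1L), "[\t,;]")[[1]][-1]
  if (anyDuplicated(hdr))
    stop(sprintf("%s: duplicate sample IDs: %s", path,
                 paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  if (ncol(dt) < 2L) stop(sprintf("%s: need a feature-ID column plus >= 1 sample", path))
  ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  bad_num <- which(!vapply(body, is.numeric, logical(1)))
  if (length(bad_num))
    stop(sprintf("%s: non-numeric values in column(s) %s", path,
                 paste(colnames(body)[bad_num], collapse = ", ")))
  X <- as.matrix(body)
  rownames(X) <- ids
  if (drop_zero_variance) {
    sdv <- apply(X, 1L, stats::sd)
    n_bad <- sum(sdv == 0)
    if (n_bad > 0) {
      message(sprintf("%s: dropped %d zero-variance feature(s)", basename(path), n_bad))
      X <- X[sdv > 0, , drop = FALSE]
    }
  }
  X
}

#' Write a view matrix as delimited text
#'
#' @param X features x samples matrix with dimnames.
#' @param path output path; tab-separated with a `feature_id` first column.
#' @export
write_view_matrix <- function(X, path) {
  dt <- data.frame(feature_id = rownames(X) %||% sprintf("F%04d", seq_len(nrow(X))),
                   X, check.names = FALSE)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Export a similarity graph as an edge list
#'
#' Writes `(sample_i, sample_j, weight)` rows for every off-diagonal entry of
#' the symmetrized graph above a threshold, for use with graph tooling.
#'
#' @param Z n x n similarity matrix with sample dimnames.
#' @param path output TSV path.
#' @param threshold minimum (symmetrized) weight to keep an edge.
#' @return Invisibly, the number of edges written.
#' @export
write_edge_list <- function(Z, path, threshold = 0) {
  W <- (Z + t(Z)) / 2
  ids <- rownames(W) %||% sprintf("S%03d", seq_len(nrow(W)))
  idx <- which(upper.tri(W) & W > threshold, arr.ind = TRUE)
  el <- data.frame(sample_i = ids[idx[, 1]], sample_j = ids[idx[, 2]],
                   weight = W[idx])
  data.table::fwrite(el, path, sep = "\t")
  invisible(nrow(el))
}

#' Read or write optimizer settings as a config file
#'
#' Serializes a [ulsl_params()] object to JSON (`.json`) or YAML
#' (`.yaml`/`.yml`, requires the `yaml` package), and back. Nested blocks
#' mirror the parameter structure (`snf`, `admm`).
#'
#' @param params a [ulsl_params()] object.
#' @param path config file path; the format follows the extension.
#' @return `write_params_file` returns `path` invisibly;
#'   `read_params_file` returns a [ulsl_params()].
#' @export
write_params_file <- function(params, path) {
  x <- lapply(unclass(params), function(v) if (is.list(v)) unclass(v) else v)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_params_file
#' @export
read_params_file <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  snf <- do.call(snf_params, x$snf %||% list())
  admm <- do.call(admm_params, x$admm %||% list())
  keep <- setdiff(names(x), c("snf", "admm"))
  x <- x[keep]
  x <- x[!vapply(x, is.null, logical(1))]
  do.call(ulsl_params, c(x, list(snf = snf, admm = admm)))
}

#' Align views on their common samples
#'
#' Takes the intersection of sample IDs across views, in first-view order,
#' and subsets every view to it.
#'
#' @param views named list of feature x sample matrices with sample colnames.
#' @return List of aligned matrices (message reports dropped samples).
#' @export
align_views <- function(views) {
  common <- Reduce(intersect, lapply(views, colnames))
  if (length(common) == 0L) stop("views share no samples")
  common <- colnames(views[[1]])[colnames(views[[1]]) %in% common]
  dropped <- sum(vapply(views, ncol, integer(1))) - length(common) * length(views)
  if (dropped > 0)
    message(sprintf("aligned views on %d common samples (%d view-columns dropped)",
                    length(common), dropped))
  lapply(views, function(X) X[, common, drop = FALSE])
}

#' Write a synthetic dataset to a directory
#'
#' Emits one TSV per view, a labels TSV (`sample_id`, `label`) and a JSON
#' sidecar recording the generating configuration.
#'
#' @param dataset a [multi_omics()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (v in seq_along(dataset$views)) {
    p <- file.path(dir, sprintf("view%d.tsv", v))
    write_view_matrix(dataset$views[[v]], p)
    paths <- c(paths, p)
  }
  if (!is.null(dataset$true_labels)) {
    p <- file.path(dir, "labels.tsv")
    data.table::fwrite(data.frame(sample_id = dataset$sample_ids,
                                  label = dataset$true_labels), p, sep = "\t")
    paths <- c(paths, p)
  }
  if (!is.null(dataset$config)) {
    p <- file.path(dir, "sim_config.json")
    jsonlite::write_json(unclass(dataset$config), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run the full pipeline from files on disk
#'
#' Reads the view matrices, aligns samples, fits the model, chooses the
#' cluster number (gap statistic over the sample-size-dependent search range
#' by default, or the eigengap heuristic), clusters the learned graph, and
#' writes: `Z.tsv`, `H.tsv` (samples x d embedding), `labels.tsv`,
#' `objective_trace.csv` and `report.json`.
#'
#' @param view_paths character vector of view-matrix files.
#' @param out_dir output directory.
#' @param params a [ulsl_params()].
#' @param k optional fixed cluster number; otherwise selected automatically.
#' @param k_method `"gap"` or `"eigengap"` when `k` is not given.
#' @param log1p_views indices of views to `log1p`-transform before fitting
#'   (for count-like modalities).
#' @return Invisibly, the report as a list.
#' @export
run_pipeline <- function(view_paths, out_dir, params = ulsl_params(),
                         k = NULL, k_method = c("gap", "eigengap"),
                         log1p_views = integer(0)) {
  k_method <- match.arg(k_method)
  missing <- view_paths[!file.exists(view_paths)]
  if (length(missing))
    stop(sprintf("input stage: missing view file(s): %s", paste(missing, collapse = ", ")))
  views <- lapply(view_paths, read_view_matrix)
  for (v in log1p_views) views[[v]] <- log1p(views[[v]])
  views <- align_views(views)
  dataset <- multi_omics(views)
  fit <- ulsl_fit(dataset, params)
  n <- length(dataset$sample_ids)
  if (is.null(k)) {
    kr <- k_search_range(n)
    k <- if (k_method == "eigengap") {
      eigengap_k(fit$Z, kr[1], kr[2])
    } else {
      emb <- spectral_cluster(fit$Z, kr[2], seed = params$seed)$embedding
      gap_statistic_k(emb, kr[1], kr[2], seed = params$seed)
    }
  }
  cl <- spectral_cluster(fit$Z, k, seed = params$seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Zo <- fit$Z
  dimnames(Zo) <- list(dataset$sample_ids, dataset$sample_ids)
  write_view_matrix(Zo, file.path(out_dir, "Z.tsv"))
  Ht <- t(fit$H)
  dimnames(Ht) <- list(dataset$sample_ids, sprintf("dim%02d", seq_len(nrow(fit$H))))
  data.table::fwrite(data.frame(sample_id = dataset$sample_ids, Ht,
                                check.names = FALSE),
                     file.path(out_dir, "H.tsv"), sep = "\t")
  data.table::fwrite(data.frame(sample_id = dataset$sample_ids, cluster = cl$labels),
                     file.path(out_dir, "labels.tsv"), sep = "\t")
  data.table::fwrite(data.frame(iteration = seq_along(fit$objective_trace),
                                objective = fit$objective_trace),
                     file.path(out_dir, "objective_trace.csv"))
  report <- list(views = view_paths, n_samples = n, k = k, k_method = k_method,
                 alpha = fit$alpha, beta = params$beta, d = params$d,
                 seed = params$seed, n_iterations = fit$n_iterations,
                 converged = fit$converged,
                 final_objective = utils::tail(fit$objective_trace, 1),
                 version = as.character(utils::packageVersion("ulsl")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
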