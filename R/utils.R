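#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded internals (initialization, k-means restarts, reference draws) do not
#' perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to run unseeded.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Frobenius norm
fnorm <- function(M) sqrt(sum(M * M))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

#' Squared Euclidean distances between columns
#'
#' @param X numeric matrix (features x samples).
#' @return n x n matrix of pairwise squared distances between columns of `X`.
#' @keywords internal
col_sqdist <- function(X) {
  ss <- colSums(X^2)
  D2 <- outer(ss, ss, "+") - 2 * crossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}
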