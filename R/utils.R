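# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Restores (or removes) the global \code{.Random.seed} afterwards so that
#' seeded operations do not perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Stratified index split
#'
#' Draws a seeded random partition of 1..n into a "train" part holding
#' roughly `ratio` of each class and a "test" part with the rest.
#' Rounding is per class (floor at least 1, at most n_c - 1 so both parts
#' retain every class).
#' @noRd
stratified_split <- function(y, ratio, seed = NULL) {
  with_seed(seed, {
    idx_train <- integer(0)
    for (cls in sort(unique(y))) {
      pos <- which(y == cls)
      n_c <- length(pos)
      n_tr <- max(1L, min(n_c - 1L, round(ratio * n_c)))
      idx_train <- c(idx_train, sample(pos, n_tr))
    }
    idx_train <- sort(idx_train)
    list(train = idx_train, test = setdiff(seq_along(y), idx_train))
  })
}

#' Stratified fold assignment for cross-validation
#' @noRd
stratified_folds <- function(y, n_folds, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in sort(unique(y))) {
      pos <- sample(which(y == cls))
      fold[pos] <- rep_len(seq_len(n_folds), length(pos))
    }
    fold
  })
}

#' Unit-normalize a vector
#' @noRd
unitize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

#' Absolute cosine similarity between two vectors
#' @noRd
abs_cosine <- function(a, b) {
  abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Moore-Penrose pseudo-inverse via SVD with relative singular-value cutoff
#' @noRd
pinv_svd <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
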