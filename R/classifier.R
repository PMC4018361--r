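# Gaussian linear (Bayes) classifier on projected scores, and the
# imbalance-aware confusion metrics used to compare methods.

#' Fit a Gaussian linear classifier on projected scores
#'
#' The linear Bayes rule: class-conditional Gaussians with a pooled
#' covariance matrix and empirical class priors, applied to the
#' d-dimensional scores a dimension-reduction method produced. A diagonal
#' (naive) covariance variant is available. A singular pooled covariance is
#' regularized by a small ridge (1e-8 of the mean diagonal), with a warning.
#'
#' @param scores n x d numeric score matrix (a vector is taken as one column).
#' @param y labels coded -1/+1 (both classes must be present).
#' @param diagonal logical; use a diagonal pooled covariance (naive Bayes).
#' @return object of class \code{"gaussian_linear_classifier"}: list with
#'   \code{means} (2 x d), \code{cov} (pooled d x d), \code{priors},
#'   \code{labels = c(-1, 1)}.
#' @export
fit_classifier <- function(scores, y, diagonal = FALSE) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(y))
  i1 <- y == -1
  if (!any(i1) || all(i1)) stop("both classes must be present")
  n1 <- sum(i1); n2 <- sum(!i1); d <- ncol(scores)
  m1 <- colMeans(scores[i1, , drop = FALSE])
  m2 <- colMeans(scores[!i1, , drop = FALSE])
  C1 <- crossprod(sweep(scores[i1, , drop = FALSE], 2L, m1, "-"))
  C2 <- crossprod(sweep(scores[!i1, , drop = FALSE], 2L, m2, "-"))
  pooled <- (C1 + C2) / max(1L, n1 + n2 - 2L)
  if (diagonal) pooled <- diag(diag(pooled), d, d)
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    ridge <- 1e-8 * mean(diag(pooled)) + .Machine$double.xmin
    warning("singular pooled covariance; adding ridge ", format(ridge))
    pooled <- pooled + diag(ridge, d, d)
    inv <- solve(pooled)
  }
  structure(
    list(means = rbind(`-1` = m1, `1` = m2), cov = pooled, cov_inv = inv,
         priors = c(`-1` = n1 / (n1 + n2), `1` = n2 / (n1 + n2)),
         labels = c(-1, 1), diagonal = diagonal),
    class = "gaussian_linear_classifier"
  )
}

#' @describeIn fit_classifier predict class labels (-1/+1) for new scores by
#'   the larger linear discriminant value
#'   \eqn{x^T \Sigma^{-1}\mu_c - \mu_c^T \Sigma^{-1}\mu_c / 2 + \log \pi_c}.
#' @param object fitted classifier.
#' @param newdata q x d score matrix.
#' @param ... unused.
#' @export
predict.gaussian_linear_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1L)
  newdata <- as.matrix(newdata)
  g <- vapply(1:2, function(cls) {
    mu <- object$means[cls, ]
    a <- drop(object$cov_inv %*% mu)
    drop(newdata %*% a) - 0.5 * sum(mu * a) + log(object$priors[cls])
  }, numeric(nrow(newdata)))
  if (is.null(dim(g))) g <- matrix(g, ncol = 2L)
  object$labels[max.col(g, ties.method = "first")]
}

#' Accuracy, G-Mean and F-Value from predictions
#'
#' The positive class is the one coded +1. G-Mean is the geometric mean of
#' sensitivity and specificity (0 if either class is missed entirely);
#' F-Value is the harmonic mean of precision and recall. When no positive
#' predictions exist, precision is undefined and the F-Value is reported as
#' 0 with a flag; a class absent from \code{y_true} flags the affected
#' metrics as undefined (NA).
#'
#' @param y_true,y_pred label vectors coded -1/+1, same length.
#' @param positive the positive label (default +1).
#' @return list with \code{acc}, \code{gmean}, \code{fvalue} and a character
#'   vector \code{flags} describing any degenerate convention applied.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = 1) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  pos <- y_true == positive
  tp <- sum(pos & y_pred == positive)
  fn <- sum(pos & y_pred != positive)
  tn <- sum(!pos & y_pred != positive)
  fp <- sum(!pos & y_pred == positive)
  acc <- (tp + tn) / length(y_true)
  flags <- character(0)
  if (!any(pos) || all(pos)) {
    flags <- c(flags, "class absent from y_true; gmean/fvalue undefined")
    return(list(acc = acc, gmean = NA_real_, fvalue = NA_real_, flags = flags))
  }
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  gmean <- sqrt(tpr * tnr)
  if (tp + fp == 0L) {
    flags <- c(flags, "no predicted positives; fvalue set to 0")
    fvalue <- 0
  } else {
    prec <- tp / (tp + fp)
    fvalue <- if (prec + tpr == 0) 0 else 2 * prec * tpr / (prec + tpr)
  }
  list(acc = acc, gmean = gmean, fvalue = fvalue, flags = flags)
}
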