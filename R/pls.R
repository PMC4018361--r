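# NIPALS partial least squares: single-component extraction, deflation,
# regression-coefficient assembly, prediction.

#' Extract one NIPALS component
#'
#' One round of the alternating NIPALS iteration on already-centered data:
#' repeat \eqn{w \propto X^T u} (normalized), \eqn{t = X w},
#' \eqn{q \propto Y^T t} (normalized), \eqn{u = Y q} until the relative
#' change in \eqn{t} falls below \code{tol}. Afterwards the X loading
#' \eqn{p = X^T t / (t^T t)} and inner coefficient
#' \eqn{b = u^T t / (t^T t)} are computed. For a single-column Y the loop
#' converges in one pass and \eqn{w \propto X^T y} exactly.
#'
#' The sign of each component is fixed so that the largest-magnitude entry
#' of \eqn{w} is positive (NIPALS signs are otherwise arbitrary); \eqn{t},
#' \eqn{p}, \eqn{q} and \eqn{u} are flipped consistently, leaving \eqn{b}
#' and all reconstructions unchanged.
#'
#' @param Xc centered n x k matrix (not all zero).
#' @param Yc centered n x m matrix (a vector is taken as one column).
#' @param tol relative convergence tolerance on the score vector t.
#' @param max_iter iteration cap; non-convergence returns the current
#'   iterate with a warning.
#' @return list with \code{w}, \code{t}, \code{p}, \code{q}, \code{u},
#'   \code{b_inner}, \code{iterations}, \code{converged}.
#' @export
nipals_component <- function(Xc, Yc, tol = 1e-10, max_iter = 500L) {
  Xc <- as.matrix(Xc)
  if (is.null(dim(Yc))) Yc <- matrix(Yc, ncol = 1L)
  m <- ncol(Yc)
  # start from the Y column with the largest sum of squares
  u <- Yc[, which.max(colSums(Yc^2))]
  t_old <- NULL
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    w <- drop(crossprod(Xc, u))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("zero weight: X^T u vanished (no X-Y covariance)")
    w <- w / nw
    t <- drop(Xc %*% w)
    q <- drop(crossprod(Yc, t))
    q <- q / sqrt(sum(q^2))
    u <- drop(Yc %*% q)
    if (m == 1L) { converged <- TRUE; break }  # one-pass for a single column
    if (!is.null(t_old) &&
        sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t_old^2))) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iter) break
    t_old <- t
  }
  if (!converged) {
    warning("NIPALS did not converge in ", max_iter,
            " iterations; returning current iterate")
  }
  tt <- sum(t^2)
  p <- drop(crossprod(Xc, t)) / tt
  b_inner <- sum(u * t) / tt
  # sign convention: largest-magnitude entry of w positive
  s <- sign(w[which.max(abs(w))])
  if (s < 0) { w <- -w; t <- -t; p <- -p; q <- -q; u <- -u }
  list(w = w, t = t, p = p, q = q, u = u, b_inner = b_inner,
       iterations = iterations, converged = converged)
}

#' Fit a PLS regression model by NIPALS
#'
#' Centers X and Y (scaling optional, off by default), then extracts
#' \code{n_lv} components, deflating after each: \eqn{X \leftarrow X - t p^T},
#' \eqn{Y \leftarrow Y - b\, t q^T}. Extraction stops early with a warning
#' if the X residual is numerically exhausted. The assembled coefficient
#' matrix \eqn{B = W (P^T W)^{-1} \mathrm{diag}(b)\, Q^T} maps centered X to
#' predicted centered Y.
#'
#' @param X n x k predictor matrix.
#' @param Y response matrix or vector (n x m).
#' @param n_lv number of latent variables to extract
#'   (1 <= n_lv <= min(n - 1, k)).
#' @param center,scale preprocessing flags (centering should stay on;
#'   the NIPALS identities presume centered data).
#' @param tol,max_iter convergence controls for \code{\link{nipals_component}}.
#' @return object of class \code{"pls_model"}: list with matrices \code{W}
#'   (k x a weights, unit columns), \code{T} (n x a X-scores), \code{P}
#'   (k x a X-loadings), \code{U} (n x a Y-scores), \code{Q} (m x a
#'   Y-loadings), inner coefficients \code{b}, assembled coefficients
#'   \code{B} (k x m), residuals \code{X_residual}, \code{Y_residual},
#'   extracted count \code{a}, and the centering transforms.
#' @export
fit_pls <- function(X, Y, n_lv, center = TRUE, scale = FALSE,
                    tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  n <- nrow(X); k <- ncol(X)
  stopifnot(nrow(Y) == n)
  if (n_lv < 1L || n_lv > min(n - 1L, k)) {
    stop("n_lv must lie in 1..min(n-1, k) = 1..", min(n - 1L, k))
  }
  cx <- fit_center(X, scale = scale)
  cy <- fit_center(Y, scale = FALSE)
  if (!center) {
    cx$column_means[] <- 0
    cy$column_means[] <- 0
  }
  E <- apply_center(cx, X)
  F_ <- apply_center(cy, Y)
  x_ss0 <- sum(E^2)
  W <- P <- matrix(0, k, 0)
  Tm <- U <- matrix(0, n, 0)
  Q <- matrix(0, ncol(Y), 0)
  b <- numeric(0)
  for (i in seq_len(n_lv)) {
    if (sum(E^2) < 1e-10 * max(x_ss0, .Machine$double.eps)) {
      warning("X residual exhausted after ", i - 1L,
              " components; requested ", n_lv)
      break
    }
    comp <- nipals_component(E, F_, tol = tol, max_iter = max_iter)
    W <- cbind(W, comp$w); Tm <- cbind(Tm, comp$t); P <- cbind(P, comp$p)
    U <- cbind(U, comp$u); Q <- cbind(Q, comp$q); b <- c(b, comp$b_inner)
    E <- E - tcrossprod(comp$t, comp$p)
    F_ <- F_ - comp$b_inner * tcrossprod(comp$t, comp$q)
  }
  model <- structure(
    list(W = W, T = Tm, P = P, U = U, Q = Q, b = b, B = NULL,
         X_residual = E, Y_residual = F_, a = length(b),
         center_x = cx, center_y = cy),
    class = "pls_model"
  )
  model$B <- regression_coefficients(model)
  model
}

#' Assemble PLS regression coefficients
#'
#' \eqn{B = W (P^T W)^{-1} \mathrm{diag}(b)\, Q^T}, the closed form mapping
#' centered predictors to fitted centered responses. For a single component
#' and a single response column, B is collinear with the weight vector w.
#'
#' @param model a fitted \code{"pls_model"}.
#' @return k x m coefficient matrix.
#' @export
regression_coefficients <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$a < 1L) stop("model has no extracted components")
  PW <- crossprod(model$P, model$W)
  R <- tryCatch(solve(PW),
                error = function(e) {
                  d <- abs(diag(qr.R(qr(PW))))
                  stop("P^T W numerically singular near component ",
                       which.min(d), ": ", conditionMessage(e))
                })
  model$W %*% R %*% (model$b * t(model$Q))
}

#' Predict responses for new samples
#'
#' \eqn{\hat Y = (X_{new} - \bar x)\, B + \bar y} using the training
#' centering parameters.
#'
#' @param model a fitted \code{"pls_model"}.
#' @param X_new q x k matrix (or single sample vector).
#' @return q x m matrix of predictions.
#' @export
pls_predict <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  Xc <- apply_center(model$center_x, X_new)
  sweep(Xc %*% model$B, 2L, model$center_y$column_means, "+")
}

#' Score new samples on the fitted PLS components
#'
#' \eqn{T_{new} = (X_{new} - \bar x)\, W (P^T W)^{-1}}; on the training data
#' this reproduces the stored score matrix T.
#'
#' @param model a fitted \code{"pls_model"}.
#' @param X_new q x k matrix.
#' @return q x a score matrix.
#' @export
pls_scores <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  Xc <- apply_center(model$center_x, X_new)
  Xc %*% model$W %*% solve(crossprod(model$P, model$W))
}
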