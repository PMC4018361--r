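# LDA-PLS: LDA projection direction corrected per component by PLS
# regression of the projected values on X; ex-LDA-PLS: lambda-blended
# direction between the LDA and LDA-PLS solutions with grid search.

#' Fit an LDA-PLS model
#'
#' Per outer component i, on the current residual matrix X(i) (column-centered
#' at the first stage):
#' \enumerate{
#'   \item compute the LDA direction w(i) of (X(i), y);
#'   \item project: c(i) = X(i) w(i);
#'   \item regress c(i) on X(i) by NIPALS-PLS with \code{n_lv} latent
#'     variables and take the coefficient vector B(i) as the corrected
#'     discriminant direction;
#'   \item deflate along the extracted direction's score,
#'     t(i) = X(i) B(i) / ||X(i) B(i)||, p(i) = X(i)' t(i),
#'     X(i+1) = X(i) - t(i) p(i)'.
#' }
#' The number of PLS latent variables steers how far B(i) departs from w(i):
#' with one latent variable B is collinear with X'X w, with as many latent
#' variables as the rank of X it collapses back onto w itself.
#'
#' Each B(i) is oriented like the LDA direction (projected mean of the +1
#' class not smaller than that of the -1 class) so blending and classifier
#' thresholds are reproducible. An alternative deflation along the LDA score
#' X(i) w(i) is exposed for sensitivity analysis.
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @param n_lv latent variables of the inner PLS regression (>= 1).
#' @param n_components number of outer LDA-PLS components (>= 1).
#' @param deflation \code{"pls_score"} (default) or \code{"lda_score"}.
#' @param rtol singular-value cutoff passed to the LDA pseudo-inverse.
#' @return object of class \code{"lda_pls"}: list with \code{w_lda} (list of
#'   unit vectors), \code{B} (list of coefficient vectors), \code{scores_t},
#'   \code{loadings_p}, \code{score_norms} (the ||X(i) B(i)|| used for
#'   deflation of new samples), \code{n_lv}, \code{n_components},
#'   \code{center} (the centering transform).
#' @export
fit_lda_pls <- function(dataset, n_lv, n_components = 1L,
                        deflation = c("pls_score", "lda_score"),
                        rtol = 1e-10) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  deflation <- match.arg(deflation)
  if (n_lv < 1L) stop("n_lv must be >= 1")
  if (n_components < 1L) stop("n_components must be >= 1")
  y <- dataset$y
  ctr <- fit_center(dataset$X)
  Xi <- apply_center(ctr, dataset$X)
  x_norm0 <- sqrt(sum(Xi^2))
  w_lda <- B <- Tl <- Pl <- list()
  norms <- numeric(0)
  for (i in seq_len(n_components)) {
    if (sqrt(sum(Xi^2)) < 1e-10 * x_norm0) {
      warning("residual exhausted after ", i - 1L,
              " components; requested ", n_components)
      break
    }
    w_i <- tryCatch(lda_direction_xy(Xi, y, rtol = rtol),
                    error = function(e) e)
    if (inherits(w_i, "error")) {
      warning("LDA degenerate at component ", i, " (",
              conditionMessage(w_i), "); returning ", i - 1L, " components")
      break
    }
    c_i <- drop(Xi %*% w_i)
    lv_i <- min(n_lv, nrow(Xi) - 1L, ncol(Xi))
    pm <- fit_pls(Xi, c_i, n_lv = lv_i, center = TRUE)
    B_i <- drop(pm$B)
    # orient B like the LDA direction: +1 class projects higher
    if (mean((Xi %*% B_i)[y == 1]) < mean((Xi %*% B_i)[y == -1])) B_i <- -B_i
    if (!all(is.finite(B_i)) || all(B_i == 0)) {
      warning("PLS coefficients degenerate at component ", i,
              "; returning ", i - 1L, " components")
      break
    }
    dir_i <- if (deflation == "pls_score") B_i else w_i
    s_i <- drop(Xi %*% dir_i)
    ns <- sqrt(sum(s_i^2))
    t_i <- s_i / ns
    p_i <- drop(crossprod(Xi, t_i))
    w_lda[[i]] <- w_i; B[[i]] <- B_i
    Tl[[i]] <- t_i; Pl[[i]] <- p_i; norms <- c(norms, ns)
    Xi <- Xi - tcrossprod(t_i, p_i)
  }
  if (length(B) == 0L) stop("no LDA-PLS components could be extracted")
  structure(
    list(w_lda = w_lda, B = B, scores_t = Tl, loadings_p = Pl,
         score_norms = norms, n_lv = n_lv, n_components = length(B),
         deflation = deflation, center = ctr),
    class = "lda_pls"
  )
}

#' Project samples onto fitted directions
#'
#' Generic: maps new samples into the low-dimensional score space of a
#' fitted dimension-reduction model.
#' @param object a fitted model.
#' @param X_new q x k matrix of new samples (original feature space).
#' @param ... passed to methods.
#' @return q x d numeric score matrix.
#' @export
project <- function(object, X_new, ...) UseMethod("project")

#' @describeIn project column i is the current deflation-consistent residual
#'   of \code{X_new} multiplied by B(i); stage residuals use the stored
#'   loading/score-norm pairs, so projecting the training data reproduces
#'   the fit.
#' @export
project.lda_pls <- function(object, X_new, ...) {
  Xc <- apply_center(object$center, X_new)
  out <- matrix(0, nrow(Xc), object$n_components)
  for (i in seq_len(object$n_components)) {
    out[, i] <- drop(Xc %*% object$B[[i]])
    dir_i <- if (object$deflation == "pls_score") object$B[[i]] else object$w_lda[[i]]
    t_new <- drop(Xc %*% dir_i) / object$score_norms[i]
    Xc <- Xc - tcrossprod(t_new, object$loadings_p[[i]])
  }
  out
}

#' Blend the LDA and LDA-PLS directions (ex-LDA-PLS)
#'
#' \deqn{w(\lambda) = \mathrm{normalize}\big((1-\lambda)\,\hat w_{lda}
#'       + \lambda\,\hat B\big)}
#' where both inputs are unit-normalized first (their raw scales differ by an
#' arbitrary proportionality constant, which would otherwise distort the
#' meaning of \eqn{\lambda}). \eqn{\lambda = 0} returns the LDA direction,
#' \eqn{\lambda = 1} the LDA-PLS direction.
#'
#' @param w_lda length-k LDA direction (any nonzero scale).
#' @param B_ldapls length-k LDA-PLS coefficient vector (any nonzero scale).
#' @param lambda blend weight in [0, 1].
#' @return object of class \code{"ex_lda_pls_direction"}: list with
#'   \code{lambda} and unit vector \code{w_combined}.
#' @export
combine_ex <- function(w_lda, B_ldapls, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  wh <- unitize(as.numeric(w_lda))
  bh <- unitize(as.numeric(B_ldapls))
  v <- (1 - lambda) * wh + lambda * bh
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) {
    stop("degenerate blend: inputs are antiparallel at this lambda")
  }
  structure(list(lambda = lambda, w_combined = v / nv),
            class = "ex_lda_pls_direction")
}

#' Grid search for the blend weight lambda
#'
#' Splits the training set 50/50 (stratified, seeded) into a selection half
#' and a verification half; fits the LDA direction and a one-component
#' LDA-PLS model on the selection half; then, for every lambda on the grid
#' \{0, step, 2 step, ..., 1\}, projects both halves onto the blended
#' direction, fits the Gaussian linear classifier on the selection-half
#' scores and records its accuracy on the verification half. A single
#' traversal of the grid is performed. Ties are broken toward the smallest
#' lambda (minimal departure from plain LDA).
#'
#' @param train a \code{\link{labeled_dataset}}.
#' @param n_lv latent variables for the inner PLS of LDA-PLS.
#' @param step grid step (default 0.001, i.e. 1001 grid points).
#' @param seed integer seed for the stratified split.
#' @param rtol pseudo-inverse cutoff for LDA.
#' @return object of class \code{"lambda_search"}: list with
#'   \code{best_lambda}, \code{grid}, \code{val_accuracy}, \code{split_info}
#'   (selection/verification indices), \code{w_lda}, \code{B} (selection-half
#'   directions), \code{n_lv}, \code{seed}.
#' @export
search_lambda <- function(train, n_lv, step = 0.001, seed = NULL,
                          rtol = 1e-10) {
  stopifnot(inherits(train, "labeled_dataset"))
  sp <- stratified_split(train$y, 0.5, seed = seed)
  y_sel <- train$y[sp$train]; y_ver <- train$y[sp$test]
  if (min(table(y_sel)) < 2L || min(table(y_ver)) < 2L) {
    stop("lambda split left a class with fewer than 2 samples; ",
         "use a larger dataset or a different seed")
  }
  d_sel <- subset_dataset(train, sp$train)
  w <- lda_direction(d_sel, rtol = rtol)$w
  fit <- fit_lda_pls(d_sel, n_lv = n_lv, n_components = 1L, rtol = rtol)
  B <- fit$B[[1]]
  wh <- unitize(w); bh <- unitize(B)
  X_sel <- train$X[sp$train, , drop = FALSE]
  X_ver <- train$X[sp$test, , drop = FALSE]
  # projections of both halves onto the two endpoint directions; the blend's
  # projection is the same convex combination (renormalization of the
  # direction rescales scores uniformly, which the classifier is invariant to)
  ps_w <- drop(X_sel %*% wh); ps_b <- drop(X_sel %*% bh)
  pv_w <- drop(X_ver %*% wh); pv_b <- drop(X_ver %*% bh)
  grid <- seq(0, 1, by = step)
  acc <- vapply(grid, function(lam) {
    s_sel <- (1 - lam) * ps_w + lam * ps_b
    s_ver <- (1 - lam) * pv_w + lam * pv_b
    if (max(abs(s_sel)) == 0) return(NA_real_)  # degenerate blend
    clf <- fit_classifier(matrix(s_sel, ncol = 1), y_sel)
    mean(predict(clf, matrix(s_ver, ncol = 1)) == y_ver)
  }, numeric(1))
  best <- grid[which.max(acc)]  # which.max takes the first (smallest) maximum
  structure(
    list(best_lambda = best, grid = grid, val_accuracy = acc,
         split_info = list(selection = sp$train, verification = sp$test),
         w_lda = w, B = B, n_lv = n_lv, seed = seed),
    class = "lambda_search"
  )
}
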