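# Two-class linear discriminant analysis: scatter matrices and the
# SVD-pseudo-inverse discriminant direction.

#' Class mean vectors
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @return list with \code{m1} (mean of the class coded -1), \code{m2} (mean
#'   of the class coded +1) and \code{counts = c(n1, n2)}.
#' @export
class_means <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  i1 <- dataset$y == -1
  if (!any(i1) || all(i1)) stop("degenerate labels: a class is empty")
  list(m1 = colMeans(dataset$X[i1, , drop = FALSE]),
       m2 = colMeans(dataset$X[!i1, , drop = FALSE]),
       counts = c(n1 = sum(i1), n2 = sum(!i1)))
}

#' Within- and between-class scatter matrices
#'
#' For two classes with means m1, m2:
#' \deqn{S_W = \sum_i \sum_{x \in class_i} (x - m_i)(x - m_i)^T, \quad
#'       S_B = (m_1 - m_2)(m_1 - m_2)^T.}
#' Both are raw (unnormalized) sums; any positive scalar on either only
#' rescales the discriminant direction, which is renormalized downstream.
#' S_B has rank at most 1.
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @return object of class \code{"scatter_matrices"}: list with \code{S_W},
#'   \code{S_B}, \code{m1}, \code{m2}, \code{counts}.
#' @export
scatter_matrices <- function(dataset) {
  cm <- class_means(dataset)
  X <- dataset$X
  i1 <- dataset$y == -1
  D1 <- sweep(X[i1, , drop = FALSE], 2L, cm$m1, "-")
  D2 <- sweep(X[!i1, , drop = FALSE], 2L, cm$m2, "-")
  S_W <- crossprod(D1) + crossprod(D2)
  d <- cm$m1 - cm$m2
  S_B <- tcrossprod(d)
  structure(list(S_W = S_W, S_B = S_B, m1 = cm$m1, m2 = cm$m2,
                 counts = cm$counts),
            class = "scatter_matrices")
}

# Matrix-level direction used by both the public API and LDA-PLS residual
# loops (which carry y alongside a deflated X that is no longer a dataset).
lda_direction_xy <- function(X, y, rtol = 1e-10) {
  i1 <- y == -1
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  D1 <- sweep(X[i1, , drop = FALSE], 2L, m1, "-")
  D2 <- sweep(X[!i1, , drop = FALSE], 2L, m2, "-")
  S_W <- crossprod(D1) + crossprod(D2)
  if (max(abs(S_W)) == 0) stop("no within-class variation: S_W is the zero matrix")
  w <- drop(pinv_svd(S_W, rtol = rtol) %*% (m2 - m1))
  if (sqrt(sum(w^2)) < .Machine$double.eps^0.75 * sqrt(sum((m2 - m1)^2))) {
    stop("degenerate direction: the class-mean difference lies in the ",
         "discarded null space of S_W (pseudo-inverse cutoff rtol = ", rtol, ")")
  }
  w <- unitize(w)
  # orient so the positive class has the larger projected mean
  if (sum(w * m2) < sum(w * m1)) w <- -w
  w
}

#' LDA discriminant direction
#'
#' Two-class closed form: because \eqn{S_B} has rank 1, the generalized
#' eigenproblem reduces to \eqn{w \propto S_W^{+} (m_2 - m_1)}, computed with
#' an SVD pseudo-inverse so the small-sample regime (k > n, singular
#' \eqn{S_W}) is handled by the same route. Singular values below
#' \code{rtol} times the largest are treated as zero. The returned vector has
#' unit norm and is oriented so the projected mean of the \code{+1} class is
#' not smaller than that of the \code{-1} class.
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @param rtol relative singular-value cutoff for the pseudo-inverse.
#' @return object of class \code{"lda_direction"}: list with \code{w}
#'   (unit vector) and \code{rtol}.
#' @examples
#' d <- labeled_dataset(rbind(c(1,0), c(3,0), c(2,1), c(2,-1),
#'                            c(6,0), c(8,0), c(7,1), c(7,-1)),
#'                      rep(c(-1, 1), each = 4))
#' lda_direction(d)$w # (1, 0): isotropic scatter, direction = mean difference
#' @export
lda_direction <- function(dataset, rtol = 1e-10) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  w <- lda_direction_xy(dataset$X, dataset$y, rtol = rtol)
  structure(list(w = w, rtol = rtol), class = "lda_direction")
}
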