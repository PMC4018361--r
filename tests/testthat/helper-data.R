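# Fixture builders used across test files. All are pure functions of a seed.

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Two-class Gaussian dataset with a mean shift along `shift` (length k).
random_dataset <- function(n, k, shift = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(shift)) shift <- rnorm(k) / 2
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(n * k), n, k) + outer(y, shift)
  labeled_dataset(X, y)
}

# The 8-point isotropic-scatter configuration with known class means,
# scatter matrices and discriminant direction.
eight_point_dataset <- function() {
  X <- rbind(c(1, 0), c(3, 0), c(2, 1), c(2, -1),
             c(6, 0), c(8, 0), c(7, 1), c(7, -1))
  labeled_dataset(X, rep(c(-1, 1), each = 4))
}

# Training accuracy of the Gaussian linear classifier on 1-D projections
# of X along direction w.
direction_train_acc <- function(X, y, w) {
  s <- X %*% matrix(w, ncol = 1)
  clf <- fit_classifier(s, y)
  mean(predict(clf, s) == y)
}

# Accuracy over the whole lambda grid for blends of w_lda and B on the
# training data itself (classifier refitted per grid point). Uses the
# projection-space shortcut: blending directions blends projections.
blend_grid_train_acc <- function(d, n_lv = 1, step = 0.001) {
  w <- lda_direction(d)$w
  B <- fit_lda_pls(d, n_lv = n_lv)$B[[1]]
  pw <- drop(d$X %*% (w / sqrt(sum(w^2))))
  pb <- drop(d$X %*% (B / sqrt(sum(B^2))))
  grid <- seq(0, 1, by = step)
  acc <- vapply(grid, function(lam) {
    s <- (1 - lam) * pw + lam * pb
    clf <- fit_classifier(matrix(s, ncol = 1), d$y)
    mean(predict(clf, matrix(s, ncol = 1)) == d$y)
  }, numeric(1))
  list(grid = grid, acc = acc, lda_acc = direction_train_acc(d$X, d$y, w))
}
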