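test_that("two latent variables on full-rank 2-D data reproduce the LDA direction", {
  for (s in 1:25) {
    d <- random_dataset(50, 2, seed = 200 + s)
    w <- lda_direction(d)$w
    B <- fit_lda_pls(d, n_lv = 2)$B[[1]]
    expect_gt(abs_cosine(B, w), 1 - 1e-6)
  }
})

test_that("one latent variable gives B proportional to X'X w_lda", {
  for (s in 1:25) {
    d <- random_dataset(60, 8, seed = 300 + s)
    w <- lda_direction(d)$w
    Xc <- scale(d$X, scale = FALSE)
    ref <- drop(crossprod(Xc) %*% w)
    B <- fit_lda_pls(d, n_lv = 1)$B[[1]]
    expect_gt(abs_cosine(B, ref), 1 - 1e-6)
  }
})

test_that("with as many latent variables as the rank, B collapses onto w_lda", {
  for (s in 1:10) {
    d <- random_dataset(60, 6, seed = 400 + s)
    w <- lda_direction(d)$w
    B <- fit_lda_pls(d, n_lv = 6)$B[[1]]
    expect_gt(abs_cosine(B, w), 1 - 1e-6)
  }
})

test_that("projection of training data reproduces the fitted scores", {
  d <- random_dataset(80, 10, seed = 17)
  fm <- fit_lda_pls(d, n_lv = 3, n_components = 3)
  expect_equal(fm$n_components, 3L)
  # stage-wise self-consistency: recompute column i from the stage residual
  Xc <- scale(d$X, scale = FALSE)
  S <- project(fm, d$X)
  for (i in 1:3) {
    expect_equal(S[, i], drop(Xc %*% fm$B[[i]]), tolerance = 1e-8)
    Xc <- Xc - tcrossprod(drop(Xc %*% fm$B[[i]]) / fm$score_norms[i],
                          fm$loadings_p[[i]])
  }
  # deflation scores are mutually orthogonal
  Tm <- do.call(cbind, fm$scores_t)
  G <- crossprod(Tm)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # the training centroid projects to zero
  expect_equal(drop(project(fm, colMeans(d$X))), rep(0, 3), tolerance = 1e-10)
  # single component: projection is just (X - means) B
  fm1 <- fit_lda_pls(d, n_lv = 3, n_components = 1)
  expect_equal(project(fm1, d$X)[, 1],
               drop(scale(d$X, scale = FALSE) %*% fm1$B[[1]]),
               tolerance = 1e-10)
})

test_that("blending endpoints, ties and degeneracies behave as specified", {
  set.seed(21)
  w <- rnorm(5); B <- rnorm(5)
  wh <- w / sqrt(sum(w^2)); bh <- B / sqrt(sum(B^2))
  expect_equal(combine_ex(w, B, 0)$w_combined, wh)
  expect_equal(combine_ex(w, B, 1)$w_combined, bh)
  # identical inputs: blend is the input for any lambda
  expect_equal(combine_ex(w, 3 * w, 0.42)$w_combined, wh)
  # interior blends are unit vectors varying continuously
  lams <- seq(0, 1, 0.1)
  V <- sapply(lams, function(l) combine_ex(w, B, l)$w_combined)
  expect_equal(colSums(V^2), rep(1, length(lams)))
  steps <- sqrt(colSums((V[, -1] - V[, -ncol(V)])^2))
  expect_lt(max(steps), 0.5)
  expect_error(combine_ex(w, B, 1.2), "lambda")
  expect_error(combine_ex(w, -w, 0.5), "degenerate blend")
})

test_that("lambda search covers the grid, dominates endpoints, and is deterministic", {
  toy <- make_toy2d(n = 400, seed = 5)
  ls1 <- search_lambda(toy, n_lv = 1, step = 0.001, seed = 9)
  expect_length(ls1$grid, 1001L)
  expect_equal(ls1$grid[1], 0)
  expect_equal(ls1$grid[1001], 1)
  best_acc <- ls1$val_accuracy[match(ls1$best_lambda, ls1$grid)]
  expect_gte(best_acc, ls1$val_accuracy[1])
  expect_gte(best_acc, ls1$val_accuracy[1001])
  # smallest-lambda tie rule
  expect_equal(ls1$best_lambda, min(ls1$grid[ls1$val_accuracy == best_acc]))
  # identical seed reproduces everything
  ls2 <- search_lambda(toy, n_lv = 1, step = 0.001, seed = 9)
  expect_identical(ls1[c("best_lambda", "val_accuracy", "split_info")],
                   ls2[c("best_lambda", "val_accuracy", "split_info")])
  # a dataset LDA separates perfectly selects lambda = 0
  d <- random_dataset(60, 2, shift = c(8, 0), seed = 33)
  ls3 <- search_lambda(d, n_lv = 1, seed = 2)
  expect_equal(ls3$best_lambda, 0)
  expect_equal(max(ls3$val_accuracy), 1)
})

test_that("lda_score deflation variant runs and differs only in later components", {
  d <- random_dataset(60, 6, seed = 55)
  f1 <- fit_lda_pls(d, n_lv = 2, n_components = 2, deflation = "pls_score")
  f2 <- fit_lda_pls(d, n_lv = 2, n_components = 2, deflation = "lda_score")
  expect_gt(abs_cosine(f1$B[[1]], f2$B[[1]]), 1 - 1e-10)  # first component shared
  expect_equal(ncol(project(f2, d$X)), 2L)
})
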