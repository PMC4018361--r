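test_that("class means and scatter matrices match the direct-summation oracle", {
  d <- eight_point_dataset()
  cm <- class_means(d)
  expect_equal(cm$m1, c(2, 0), ignore_attr = TRUE)
  expect_equal(cm$m2, c(7, 0), ignore_attr = TRUE)

  sm <- scatter_matrices(d)
  expect_equal(sm$S_W, diag(c(4, 4)), ignore_attr = TRUE)
  expect_equal(sm$S_B, rbind(c(25, 0), c(0, 0)), ignore_attr = TRUE)

  # independent brute-force oracle on a random instance
  dr <- random_dataset(30, 3, seed = 2)
  smr <- scatter_matrices(dr)
  SW <- matrix(0, 3, 3); SB <- matrix(0, 3, 3)
  for (cls in c(-1, 1)) {
    Xi <- dr$X[dr$y == cls, ]
    mi <- colMeans(Xi)
    for (r in seq_len(nrow(Xi))) SW <- SW + tcrossprod(Xi[r, ] - mi)
  }
  md <- colMeans(dr$X[dr$y == -1, ]) - colMeans(dr$X[dr$y == 1, ])
  SB <- tcrossprod(md)
  expect_equal(smr$S_W, SW, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(smr$S_B, SB, tolerance = 1e-10, ignore_attr = TRUE)
  # symmetry and positive semi-definiteness
  expect_equal(smr$S_W, t(smr$S_W))
  expect_gte(min(eigen(smr$S_W, symmetric = TRUE)$values), -1e-10)
  expect_equal(sum(eigen(smr$S_B)$values > 1e-10), 1L)  # rank 1
})

test_that("degenerate scatter inputs raise the documented errors", {
  # every sample equals its class mean -> S_W = 0
  X <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  d <- labeled_dataset(X, c(-1, -1, 1, 1))
  expect_equal(max(abs(scatter_matrices(d)$S_W)), 0)
  expect_error(lda_direction(d), "no within-class variation")
})

test_that("lda_direction solves S_W w = (m2 - m1) with unit norm and orientation", {
  d <- eight_point_dataset()
  w <- lda_direction(d)$w
  expect_equal(w, c(1, 0), tolerance = 1e-12, ignore_attr = TRUE)

  # scale invariance
  d2 <- labeled_dataset(d$X * 37.5, d$y)
  expect_equal(lda_direction(d2)$w, w, tolerance = 1e-10, ignore_attr = TRUE)

  # rotation equivariance: direction rotates with the data
  th <- 0.73
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  d3 <- labeled_dataset(d$X %*% t(R), d$y)
  expect_equal(lda_direction(d3)$w, drop(R %*% w), tolerance = 1e-10,
               ignore_attr = TRUE)

  # orientation invariant: +1 class projects higher
  for (s in 1:5) {
    dr <- random_dataset(40, 4, seed = s)
    wr <- lda_direction(dr)$w
    expect_gte(mean(dr$X[dr$y == 1, ] %*% wr), mean(dr$X[dr$y == -1, ] %*% wr))
    expect_equal(sum(wr^2), 1)
  }
})

test_that("LDA direction maximizes the Rayleigh quotient over random directions", {
  rayleigh <- function(w, sm) {
    drop(crossprod(w, sm$S_B %*% w) / crossprod(w, sm$S_W %*% w))
  }
  for (s in 1:8) {
    k <- sample(2:5, 1)
    d <- random_dataset(30, k, seed = 100 + s)
    sm <- scatter_matrices(d)
    r_opt <- rayleigh(lda_direction(d)$w, sm)
    W <- matrix(rnorm(1000 * k), 1000, k)
    W <- W / sqrt(rowSums(W^2))
    r_rand <- apply(W, 1, rayleigh, sm = sm)
    expect_gte(r_opt, max(r_rand) - 1e-12)
  }
})

test_that("SVD pseudo-inverse route agrees with the direct solve when S_W is invertible", {
  d <- random_dataset(50, 4, seed = 7)
  sm <- scatter_matrices(d)
  w_direct <- solve(sm$S_W, sm$m2 - sm$m1)
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  w_svd <- lda_direction(d)$w
  expect_gte(abs(sum(w_direct * w_svd)), 1 - 1e-8)
})

test_that("singular S_W (k > n) still yields a finite unit direction", {
  d <- make_collinear_spectra(n = 20, k = 60, small_sample = TRUE, seed = 5)
  w <- lda_direction(d)$w
  expect_true(all(is.finite(w)))
  expect_equal(sum(w^2), 1)
})

test_that("lda_direction matches MASS::lda up to sign on well-posed data", {
  skip_if_not_installed("MASS")
  d <- random_dataset(80, 5, seed = 11)
  w <- lda_direction(d)$w
  m <- MASS::lda(d$X, grouping = factor(d$y))
  expect_gte(abs_cos <- abs(sum(w * m$scaling)) /
               sqrt(sum(w^2) * sum(m$scaling^2)), 1 - 1e-8)
})
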