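# Seeded generators: the two-dimensional toy geometry that tilts plain LDA,
# and high-dimensional collinear spectra-like data.

# Largest separating margin over a fan of unit directions (2-D exact enough
# for the generator's internal separability certificate).
separation_margin_2d <- function(X, y, n_angles = 3600L) {
  th <- seq(0, pi, length.out = n_angles)
  W <- rbind(cos(th), sin(th))
  P <- X %*% W
  gap <- apply(P, 2L, function(p) {
    min(p[y == 1]) - max(p[y == -1])
  })
  gap2 <- apply(-P, 2L, function(p) {
    min(p[y == 1]) - max(p[y == -1])
  })
  max(c(gap, gap2))
}

#' Generate the two-dimensional toy dataset
#'
#' Two linearly separable classes whose pooled within-class scatter is
#' dominated by "horizontal" points. Each class is a horizontal band
#' (uniform in x over \code{[-x_spread, x_spread]}, uniform vertical noise of
#' half-width \code{band_halfwidth} around \code{+/- class_gap/2}); an
#' \code{outlier_fraction} of each class is displaced by
#' \code{+/- outlier_shift} — horizontally by \code{outlier_shift[1]} and
#' diagonally (toward the opposite class) by \code{outlier_shift[2]}, in
#' opposite senses per class. The negative class carries the full diagonal
#' lift; the positive class's lift is scaled by \code{outlier_asymmetry},
#' which breaks the central symmetry so that the pooled-covariance threshold
#' of the Gaussian linear classifier errs along the plain-LDA direction while
#' a slightly rotated direction still separates the classes perfectly.
#'
#' Defaults are frozen: with them, plain LDA attains training accuracy < 1
#' while a blended ex-LDA-PLS direction on the 0.001 grid attains 1.
#' Separability is certified internally (directional margin over an angle
#' fan must exceed \code{margin_eps}), otherwise the generator errors before
#' returning data.
#'
#' @param n total samples (split evenly between classes; default 1224).
#' @param class_gap vertical distance between band centers (default 2).
#' @param band_halfwidth half-width of the uniform vertical noise (0.3).
#' @param x_spread horizontal half-extent of the bands (3).
#' @param outlier_fraction fraction of each class displaced (0.1; must be
#'   in [0, 0.5)).
#' @param outlier_shift length-2 displacement (horizontal, diagonal lift);
#'   default c(12, 1.6).
#' @param outlier_asymmetry lift multiplier for the positive class (0.1).
#' @param margin_eps required separating margin (0.01).
#' @param seed integer seed.
#' @return a \code{\link{labeled_dataset}} with labels -1/+1 and an
#'   attribute \code{"margin"} holding the certified separating margin.
#' @export
make_toy2d <- function(n = 1224L, class_gap = 2, band_halfwidth = 0.3,
                       x_spread = 3, outlier_fraction = 0.1,
                       outlier_shift = c(12, 1.6), outlier_asymmetry = 0.1,
                       margin_eps = 0.01, seed = 1L) {
  if (n < 8L) stop("n must be at least 8")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop("outlier_fraction must lie in [0, 0.5)")
  }
  if (length(outlier_shift) == 1L) outlier_shift <- c(outlier_shift, 0)
  with_seed(seed, {
    n1 <- n %/% 2L
    n2 <- n - n1
    gen_band <- function(nc, y0) {
      cbind(stats::runif(nc, -x_spread, x_spread),
            y0 + stats::runif(nc, -band_halfwidth, band_halfwidth))
    }
    X1 <- gen_band(n1, -class_gap / 2)  # class -1
    X2 <- gen_band(n2, +class_gap / 2)  # class +1
    k1 <- round(outlier_fraction * n1)
    k2 <- round(outlier_fraction * n2)
    if (k1 > 0) {
      idx <- sample(n1, k1)
      X1[idx, 1] <- X1[idx, 1] + outlier_shift[1]
      X1[idx, 2] <- X1[idx, 2] + outlier_shift[2]
    }
    if (k2 > 0) {
      idx <- sample(n2, k2)
      X2[idx, 1] <- X2[idx, 1] - outlier_shift[1]
      X2[idx, 2] <- X2[idx, 2] - outlier_asymmetry * outlier_shift[2]
    }
    X <- rbind(X1, X2)
    y <- c(rep(-1, n1), rep(1, n2))
    margin <- separation_margin_2d(X, y)
    if (margin < margin_eps) {
      stop("configuration violates linear separability (margin ",
           format(margin), " < ", margin_eps, ")")
    }
    out <- labeled_dataset(X, y, feature_ids = c("x", "y"))
    attr(out, "margin") <- margin
    out
  })
}

#' Generate collinear spectra-like data
#'
#' Emulates the neighbor-feature collinearity of vibrational spectra: the
#' class signal lives in \code{n_informative} smooth Gaussian bumps of width
#' \code{collinearity_length} placed along the feature axis, with amplitudes
#' of alternating sign scaled by \code{class_shift/2} per class; per-sample
#' latent variation and additive white noise (both \code{noise_sd}) are
#' smoothed by the same kernel so that adjacent features stay strongly
#' correlated. With \code{small_sample = TRUE} the generator asserts
#' \code{k > n}, the regime where the within-class scatter matrix is
#' singular and the SVD pseudo-inverse route of LDA is exercised.
#'
#' @param n samples (balanced -1/+1; default 100).
#' @param k features (default 200).
#' @param n_informative number of signal bumps (default 5).
#' @param collinearity_length smoothing kernel width in feature units (10).
#' @param class_shift separation of the class mean scores (default 4).
#' @param noise_sd standard deviation of latent and additive noise (0.3).
#' @param small_sample logical; assert the k > n small-sample regime.
#' @param seed integer seed.
#' @return a \code{\link{labeled_dataset}}.
#' @export
make_collinear_spectra <- function(n = 100L, k = 200L, n_informative = 5L,
                                   collinearity_length = 10, class_shift = 4,
                                   noise_sd = 0.3, small_sample = FALSE,
                                   seed = 1L) {
  if (n_informative < 1L || k < n_informative) {
    stop("need k >= n_informative >= 1")
  }
  if (small_sample && k <= n) {
    stop("small_sample regime requires k > n")
  }
  with_seed(seed, {
    n1 <- n %/% 2L
    y <- c(rep(-1, n1), rep(1, n - n1))
    grid <- seq_len(k)
    centers <- stats::runif(n_informative, 0.05 * k, 0.95 * k)
    basis <- vapply(centers, function(c0) {
      exp(-0.5 * ((grid - c0) / collinearity_length)^2)
    }, numeric(k))                       # k x n_informative
    amp <- rep_len(c(1, -1), n_informative)
    # per-sample bump scores: class mean +/- shift/2 plus latent variation
    scores <- outer(y, amp * class_shift / 2) +
      matrix(stats::rnorm(n * n_informative, sd = noise_sd),
             n, n_informative)
    X <- scores %*% t(basis)
    if (noise_sd > 0) {
      # additive noise smoothed along the feature axis -> collinear noise
      Z <- matrix(stats::rnorm(n * k, sd = noise_sd), n, k)
      kern <- exp(-0.5 * (outer(grid, grid, "-") / collinearity_length)^2)
      kern <- kern / rowSums(kern)
      X <- X + Z %*% t(kern)
    }
    labeled_dataset(X, y,
                    feature_ids = sprintf("f%04d", grid))
  })
}
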