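# Comparative evaluation harness: method pipelines, latent-variable
# cross-validation, PCA / PLS-LDA baselines, repeated stratified splits,
# component sweeps.

#' PCA baseline by cumulative contribution rate
#'
#' Keeps the smallest number of leading principal components of the training
#' covariance whose cumulative explained-variance fraction reaches
#' \code{rate}.
#'
#' @param train_X n x k training matrix.
#' @param rate cumulative contribution threshold in (0, 1] (default 0.95).
#' @return list with \code{components} (k x d orthonormal loadings),
#'   \code{d}, and \code{center} (training column means).
#' @export
pca_baseline <- function(train_X, rate = 0.95) {
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]")
  train_X <- as.matrix(train_X)
  pc <- stats::prcomp(train_X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stop("zero total variance")
  cum <- cumsum(v) / sum(v)
  d <- which(cum >= rate - 1e-12)[1]
  list(components = pc$rotation[, seq_len(d), drop = FALSE], d = d,
       center = pc$center)
}

#' PLS-LDA baseline pipeline
#'
#' Dimension reduction first, discrimination second: fits PLS of X on the
#' labels with \code{n_lv} components, takes the score matrix T as reduced
#' features, then fits LDA on T. New samples map through the PLS scores and
#' the score-space LDA direction, yielding one-dimensional projections.
#'
#' @param train a \code{\link{labeled_dataset}}.
#' @param n_lv number of PLS latent variables.
#' @return list with the fitted \code{pls} model, score-space direction
#'   \code{w_scores}, and a \code{project(X_new)} function.
#' @export
pls_lda_baseline <- function(train, n_lv) {
  stopifnot(inherits(train, "labeled_dataset"))
  pm <- fit_pls(train$X, train$y, n_lv = n_lv)
  w_s <- lda_direction_xy(pm$T, train$y)
  proj <- function(X_new) pls_scores(pm, X_new) %*% matrix(w_s, ncol = 1L)
  list(pls = pm, w_scores = w_s, project = proj)
}

# Fit one named reduction method on a training dataset; returns a list with
# a project(X_new) closure producing the score matrix the classifier sees.
# Hyperparameters arrive resolved (no selection happens here).
fit_method <- function(method, train, n_lv = NULL, n_components = 1L,
                       pca_rate = 0.95, pca_d = NULL, lambda = NULL,
                       rtol = 1e-10) {
  switch(
    method,
    pca = {
      if (is.null(pca_d)) {
        pb <- pca_baseline(train$X, rate = pca_rate)
      } else {
        pc <- stats::prcomp(train$X, center = TRUE, scale. = FALSE)
        d <- min(pca_d, ncol(pc$rotation))
        pb <- list(components = pc$rotation[, seq_len(d), drop = FALSE],
                   d = d, center = pc$center)
      }
      list(project = function(Xn) {
        sweep(as.matrix(Xn), 2L, pb$center, "-") %*% pb$components
      }, d = pb$d)
    },
    lda = {
      w <- lda_direction(train, rtol = rtol)$w
      list(project = function(Xn) as.matrix(Xn) %*% matrix(w, ncol = 1L))
    },
    pls = {
      pm <- fit_pls(train$X, train$y, n_lv = n_lv)
      list(project = function(Xn) pls_predict(pm, Xn))
    },
    pls_lda = {
      bl <- pls_lda_baseline(train, n_lv = n_lv)
      list(project = bl$project)
    },
    lda_pls = {
      fm <- fit_lda_pls(train, n_lv = n_lv, n_components = n_components,
                        rtol = rtol)
      list(project = function(Xn) project(fm, Xn))
    },
    ex_lda_pls = {
      fm <- fit_lda_pls(train, n_lv = n_lv, n_components = n_components,
                        rtol = rtol)
      wl <- lda_direction(train, rtol = rtol)$w
      # blend the first (and, for multi-component models, every) component's
      # LDA direction with its LDA-PLS coefficient vector at the same lambda
      dirs <- lapply(seq_len(fm$n_components), function(i) {
        w_i <- if (i == 1L) wl else fm$w_lda[[i]]
        combine_ex(w_i, fm$B[[i]], lambda)$w_combined
      })
      fm_b <- fm
      fm_b$B <- dirs
      list(project = function(Xn) project(fm_b, Xn), lambda = lambda)
    },
    stop("unknown method: ", method)
  )
}

methods_with_lv <- c("pls", "pls_lda", "lda_pls", "ex_lda_pls")

#' Select the number of PLS latent variables by cross-validation
#'
#' Stratified seeded \code{n_folds}-fold cross-validation over
#' \code{lv_range}: for each candidate, the method is fitted on the training
#' folds, the Gaussian linear classifier is fitted on the projected training
#' scores, and mean validation-fold accuracy is recorded. Returns the argmax,
#' ties broken toward the smallest candidate. Candidates infeasible for the
#' fold size (lv > min(n - 1, k)) are dropped.
#'
#' @param train a \code{\link{labeled_dataset}}.
#' @param method one of \code{"pls"}, \code{"pls_lda"}, \code{"lda_pls"},
#'   \code{"ex_lda_pls"}.
#' @param lv_range integer candidates (default 1:10).
#' @param n_folds folds (default 10); every fold must retain both classes.
#' @param seed integer seed for fold assignment (and the inner lambda search
#'   of ex-LDA-PLS).
#' @param lambda_step grid step for ex-LDA-PLS's inner lambda search.
#' @return the selected latent-variable count (integer).
#' @export
cv_select_lv <- function(train, method = methods_with_lv, lv_range = 1:10,
                         n_folds = 10L, seed = NULL, lambda_step = 0.001) {
  stopifnot(inherits(train, "labeled_dataset"))
  method <- match.arg(method)
  fold <- stratified_folds(train$y, n_folds, seed = seed)
  folds_present <- sort(unique(fold))
  for (f in folds_present) {
    if (length(unique(train$y[fold != f])) < 2L) {
      stop("infeasible folds: a training fold lost a class; use fewer folds")
    }
  }
  n_min <- min(table(fold != folds_present[1]))  # smallest training part
  feasible <- lv_range[lv_range >= 1 &
                         lv_range <= min(nrow(train$X) - 1L, ncol(train$X))]
  if (length(feasible) == 0L) stop("no feasible latent-variable candidates")
  acc <- vapply(feasible, function(lv) {
    fold_acc <- vapply(folds_present, function(f) {
      tr <- subset_dataset(train, which(fold != f))
      va <- subset_dataset(train, which(fold == f))
      lam <- NULL
      if (method == "ex_lda_pls") {
        lam <- search_lambda(tr, n_lv = lv, step = lambda_step,
                             seed = seed)$best_lambda
      }
      fitted <- fit_method(method, tr, n_lv = lv, lambda = lam)
      clf <- fit_classifier(fitted$project(tr$X), tr$y)
      mean(predict(clf, fitted$project(va$X)) == va$y)
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  feasible[which.max(acc)]  # first maximum = smallest lv on ties
}

#' Repeated stratified-split comparison of reduction methods
#'
#' The full comparison protocol: for each of \code{n_runs} seeded runs the
#' data is split (stratified) into training and test parts at
#' \code{split_ratio}; per method, hyperparameters are selected strictly
#' inside the training part (latent variables by
#' \code{\link{cv_select_lv}} unless \code{n_lv} is fixed; lambda by
#' \code{\link{search_lambda}} for ex-LDA-PLS), the method is fitted, both
#' parts are projected, the Gaussian linear classifier is fitted on the
#' training scores, and accuracy (train and test), G-Mean and F-Value (test)
#' are recorded. Reported means are arithmetic means over runs. A method
#' failing in a run is excluded from that run with a recorded message.
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @param methods character vector from \code{"pca"}, \code{"lda"},
#'   \code{"pls"}, \code{"pls_lda"}, \code{"lda_pls"}, \code{"ex_lda_pls"}.
#' @param split_ratio training fraction (default 0.7).
#' @param n_runs repetitions (default 20).
#' @param seed integer; run r uses seed + r for its split and selections.
#' @param n_lv fixed latent-variable count, or \code{NULL} to select by
#'   cross-validation per run.
#' @param lv_range,n_folds cross-validation controls when \code{n_lv} is NULL.
#' @param n_components outer components for (ex-)LDA-PLS.
#' @param pca_rate cumulative contribution rate for the PCA baseline.
#' @param pca_d fixed PCA dimension overriding \code{pca_rate} (for sweeps).
#' @param lambda_step grid step of the lambda search.
#' @return object of class \code{"eval_report"}: list with \code{runs} (one
#'   row per method x run), \code{means} (per-method averages in the order
#'   Train Acc, Test Acc, G-Mean, F-Value), \code{failures}, \code{config}.
#' @export
repeated_split_eval <- function(dataset, methods, split_ratio = 0.7,
                                n_runs = 20L, seed = 1L, n_lv = NULL,
                                lv_range = 1:10, n_folds = 10L,
                                n_components = 1L, pca_rate = 0.95,
                                pca_d = NULL, lambda_step = 0.001) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  rows <- list()
  failures <- character(0)
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer(seed) + r
    sp <- stratified_split(dataset$y, split_ratio, seed = run_seed)
    tr <- subset_dataset(dataset, sp$train)
    te <- subset_dataset(dataset, sp$test)
    for (m in methods) {
      res <- tryCatch({
        lv <- n_lv
        if (is.null(lv) && m %in% methods_with_lv) {
          lv <- cv_select_lv(tr, m, lv_range = lv_range, n_folds = n_folds,
                             seed = run_seed, lambda_step = lambda_step)
        }
        if (!is.null(lv)) lv <- min(lv, nrow(tr$X) - 1L, ncol(tr$X))
        lam <- NULL
        if (m == "ex_lda_pls") {
          lam <- search_lambda(tr, n_lv = lv, step = lambda_step,
                               seed = run_seed)$best_lambda
        }
        fitted <- fit_method(m, tr, n_lv = lv, n_components = n_components,
                             pca_rate = pca_rate, pca_d = pca_d, lambda = lam)
        s_tr <- fitted$project(tr$X)
        s_te <- fitted$project(te$X)
        clf <- fit_classifier(s_tr, tr$y)
        p_tr <- predict(clf, s_tr)
        p_te <- predict(clf, s_te)
        mt <- confusion_metrics(te$y, p_te)
        data.frame(method = m, run = r,
                   train_acc = mean(p_tr == tr$y),
                   test_acc = mt$acc, gmean = mt$gmean, fvalue = mt$fvalue,
                   n_lv = if (is.null(lv)) NA_integer_ else lv,
                   lambda = if (is.null(lam)) NA_real_ else lam,
                   stringsAsFactors = FALSE)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- c(failures, sprintf("run %d, %s: %s", r, m, res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (length(rows) == 0L) stop("every method failed in every run")
  runs <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(runs, runs$method), function(g) {
    data.frame(method = g$method[1],
               train_acc = mean(g$train_acc), test_acc = mean(g$test_acc),
               gmean = mean(g$gmean, na.rm = TRUE),
               fvalue = mean(g$fvalue, na.rm = TRUE),
               n_runs = nrow(g), stringsAsFactors = FALSE)
  }))
  means <- means[match(intersect(methods, means$method), means$method), ]
  rownames(means) <- NULL
  structure(
    list(runs = runs, means = means, failures = failures,
         config = list(methods = methods, split_ratio = split_ratio,
                       n_runs = n_runs, seed = seed, n_lv = n_lv,
                       lv_range = lv_range, n_folds = n_folds,
                       n_components = n_components, pca_rate = pca_rate,
                       pca_d = pca_d, lambda_step = lambda_step)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Repeated stratified-split evaluation (",
      x$config$n_runs, " runs, ratio ", x$config$split_ratio, ")\n\n",
      sep = "")
  tab <- x$means
  tab[2:5] <- lapply(tab[2:5], round, digits = digits)
  names(tab) <- c("Algorithm", "Train Acc", "Test Acc", "G-Mean", "F-Value",
                  "Runs")
  print(tab, row.names = FALSE)
  if (length(x$failures)) {
    cat("\n", length(x$failures), " failed method-run(s) excluded\n", sep = "")
  }
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per method x run, followed by a means block (rows flagged in the
#' \code{block} column).
#' @param report an \code{"eval_report"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  runs <- cbind(block = "run", report$runs)
  means <- cbind(block = "mean", report$means[1:5],
                 run = NA, n_lv = NA, lambda = NA)
  means <- means[, c("block", "method", "run", "train_acc", "test_acc",
                     "gmean", "fvalue", "n_lv", "lambda")]
  runs <- runs[, names(means)]
  utils::write.csv(rbind(runs, means), path, row.names = FALSE)
  invisible(path)
}

#' Accuracy curves over the number of extracted components
#'
#' Runs the repeated-split protocol at each component count in
#' \code{component_range} (PCA uses that many leading principal components;
#' LDA-PLS and ex-LDA-PLS extract that many outer components) and reports
#' mean train/test accuracy per method and count.
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @param methods subset of \code{c("pca", "lda_pls", "ex_lda_pls")}.
#' @param component_range integer counts (e.g. 1:30).
#' @param ... passed to \code{\link{repeated_split_eval}} (notably
#'   \code{n_lv}, \code{n_runs}, \code{seed}).
#' @return data.frame with columns method, n_components, train_acc, test_acc.
#' @export
components_sweep <- function(dataset, methods = c("pca", "lda_pls", "ex_lda_pls"),
                             component_range = 1:30, ...) {
  stopifnot(all(methods %in% c("pca", "lda_pls", "ex_lda_pls")))
  out <- lapply(component_range, function(d) {
    rep_ <- repeated_split_eval(dataset, methods, n_components = d,
                                pca_d = d, ...)
    cbind(n_components = d,
          rep_$means[, c("method", "train_acc", "test_acc")])
  })
  res <- do.call(rbind, out)
  res[, c("method", "n_components", "train_acc", "test_acc")]
}
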