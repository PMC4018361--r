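# Labeled two-class datasets: container, delimited-file I/O, centering.

#' Construct a two-class labeled dataset
#'
#' The universal input container: an \code{n x k} numeric feature matrix
#' (rows are samples, columns are features) plus a two-class label vector.
#' Labels are recoded internally to \code{-1}/\code{+1}; for non-numeric or
#' arbitrary numeric labels the two distinct values are sorted (lexicographic
#' for character labels, numeric otherwise) and mapped in order to
#' \code{(-1, +1)}, so the mapping is deterministic. The class coded \code{+1}
#' is the "positive" class for G-Mean and F-Value.
#'
#' @param X numeric matrix (or data frame coercible to one), samples in rows.
#' @param y label vector of length \code{nrow(X)} with exactly two distinct
#'   values; each class must contain at least two samples.
#' @param feature_ids optional character vector of column identifiers.
#' @return An object of class \code{"labeled_dataset"}: a list with elements
#'   \code{X} (numeric matrix), \code{y} (numeric, values in \{-1, +1\}),
#'   \code{feature_ids}, and \code{label_values} (the original pair, ordered
#'   as (negative, positive)).
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' d$label_values # "a" -> -1, "b" -> +1
#' @export
labeled_dataset <- function(X, y, feature_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L) stop("empty dataset: X must be at least 1 x 1")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X))) stop("X contains missing or non-finite entries")
  lv <- unique(y)
  if (length(lv) != 2L) {
    stop("degenerate labels: y must contain exactly two distinct values, found ",
         length(lv))
  }
  lv <- if (is.numeric(y)) sort(lv) else sort(as.character(lv))
  y_num <- ifelse(as.character(y) == as.character(lv[1]), -1, 1)
  if (min(table(y_num)) < 2L) {
    stop("degenerate labels: each class needs at least 2 samples")
  }
  if (!is.null(feature_ids)) {
    stopifnot(length(feature_ids) == ncol(X))
    colnames(X) <- feature_ids
  }
  structure(
    list(X = X, y = as.numeric(y_num),
         feature_ids = colnames(X), label_values = lv),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features; classes %s (-1, n=%d) / %s (+1, n=%d)\n",
              nrow(x$X), ncol(x$X),
              x$label_values[1], sum(x$y == -1),
              x$label_values[2], sum(x$y == 1)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$X)

#' Subset a labeled dataset by sample index
#' @noRd
subset_dataset <- function(d, idx) {
  out <- d
  out$X <- d$X[idx, , drop = FALSE]
  out$y <- d$y[idx]
  out
}

detect_delimiter <- function(path) {
  line <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))))
  if (all(counts == 0)) stop("could not detect delimiter (tried comma/tab/semicolon)")
  c(",", "\t", ";")[which.max(counts)]
}

#' Load a labeled dataset from delimited text
#'
#' Reads a feature table (samples in rows) from CSV/TSV-style text. Labels
#' come either from a designated column of the same file (by index) or from a
#' separate single-column file. Rows containing any non-numeric or missing
#' feature value are dropped (with a message reporting the count) before the
#' dataset invariants are enforced.
#'
#' @param path_X path to the delimited feature file.
#' @param y label source: a column index into the feature file, or the path
#'   of a one-column label file aligned row-by-row with \code{path_X}.
#' @param delimiter field separator; \code{NULL} auto-detects among
#'   comma, tab and semicolon.
#' @param header logical; does the feature file carry a header row?
#' @return A \code{\link{labeled_dataset}}.
#' @export
load_labeled_delimited <- function(path_X, y, delimiter = NULL, header = FALSE) {
  if (!file.exists(path_X)) stop("file not found: ", path_X)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path_X)
  tab <- utils::read.table(path_X, sep = delimiter, header = header,
                           colClasses = "character", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (is.numeric(y) && length(y) == 1L) {
    lab <- tab[[y]]
    tab <- tab[, -y, drop = FALSE]
  } else {
    if (!file.exists(y)) stop("label file not found: ", y)
    lab <- utils::read.table(y, header = FALSE,
                             colClasses = "character")[[1]]
    if (length(lab) != nrow(tab)) stop("label file length does not match feature rows")
  }
  Xn <- suppressWarnings(
    vapply(tab, function(col) as.numeric(col), numeric(nrow(tab)))
  )
  if (nrow(tab) == 1L) Xn <- matrix(Xn, nrow = 1L)
  bad <- apply(Xn, 1L, function(r) any(!is.finite(r))) | is.na(lab)
  if (any(bad)) {
    message(sum(bad), " row(s) dropped (non-numeric or missing feature/label)")
  }
  Xn <- Xn[!bad, , drop = FALSE]
  lab <- lab[!bad]
  if (nrow(Xn) == 0L) stop("empty dataset: no rows survive cleaning")
  # preserve numeric label coding where possible
  lab_num <- suppressWarnings(as.numeric(lab))
  if (!any(is.na(lab_num))) lab <- lab_num
  labeled_dataset(Xn, lab, feature_ids = if (header) colnames(tab) else NULL)
}

#' Write a labeled dataset as delimited text
#'
#' Inverse of \code{\link{load_labeled_delimited}} with the label as the last
#' column; numeric values are printed at full precision so a round-trip
#' reproduces \code{X} at the printed precision and \code{y} exactly.
#'
#' @param dataset a \code{\link{labeled_dataset}}.
#' @param path output file path.
#' @param delimiter field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
write_labeled_delimited <- function(dataset, path, delimiter = ",") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- cbind(as.data.frame(format(dataset$X, digits = 17, trim = TRUE,
                                    scientific = TRUE)),
               label = dataset$y)
  utils::write.table(tab, path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Learn a column-centering transform
#'
#' NIPALS and the scatter computations presume column-centered data; the
#' transform is learned on training data only and re-applied to test data so
#' evaluation splits stay leakage-free. Optional unit-variance scaling is
#' available but off by default (centering alone is the package convention).
#'
#' @param X numeric matrix, or a \code{\link{labeled_dataset}} (its \code{X}
#'   is used).
#' @param scale logical; also divide columns by their training standard
#'   deviation (columns with zero variance are left unscaled).
#' @return An object of class \code{"centering_transform"} with elements
#'   \code{column_means} and (if scaling) \code{column_sds}.
#' @export
fit_center <- function(X, scale = FALSE) {
  if (inherits(X, "labeled_dataset")) X <- X$X
  X <- as.matrix(X)
  cm <- colMeans(X)
  out <- list(column_means = cm, column_sds = NULL)
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1
    out$column_sds <- sds
  }
  structure(out, class = "centering_transform")
}

#' Apply (or revert) a centering transform
#'
#' @param transform a \code{"centering_transform"} from \code{\link{fit_center}}.
#' @param X matrix (or single sample vector) with the same number of columns
#'   the transform was fitted on.
#' @param revert logical; undo the transform instead of applying it.
#' @return matrix of the same shape as \code{X}.
#' @export
apply_center <- function(transform, X, revert = FALSE) {
  stopifnot(inherits(transform, "centering_transform"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != length(transform$column_means)) {
    stop("dimension mismatch: transform expects ", length(transform$column_means),
         " columns, got ", ncol(X))
  }
  if (revert) {
    if (!is.null(transform$column_sds)) X <- sweep(X, 2L, transform$column_sds, "*")
    sweep(X, 2L, transform$column_means, "+")
  } else {
    X <- sweep(X, 2L, transform$column_means, "-")
    if (!is.null(transform$column_sds)) X <- sweep(X, 2L, transform$column_sds, "/")
    X
  }
}
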