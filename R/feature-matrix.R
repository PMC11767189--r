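#' Construct a feature matrix
#'
#' A feature matrix holds an `n x M` table of (typically log-transformed)
#' feature abundances: rows are samples, columns are features. It is the
#' input container for association-matrix construction, per-feature
#' testing and the effective-number-of-tests pipeline.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Must be finite throughout (missing-value handling belongs to IO).
#' @param sample_ids optional character vector of unique row labels.
#' @param feature_ids optional character vector of unique column labels.
#'
#' @return an object of class `feature_matrix` (a numeric matrix with
#'   mandatory unique dimnames).
#' @export
feature_matrix <- function(values, sample_ids = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (nrow(values) < 2L) stop("need at least 2 samples")
  if (ncol(values) < 1L) stop("need at least 1 feature")
  if (anyNA(values) || !all(is.finite(values)))
    stop("feature matrix contains missing or non-finite values; ",
         "handle missingness at ingest")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the number of rows")
  if (length(feature_ids) != ncol(values) || anyDuplicated(feature_ids))
    stop("feature_ids must be unique and match the number of columns")
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  class(values) <- c("feature_matrix", "matrix", "array")
  values
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n", nrow(x), ncol(x)))
  invisible(x)
}

# Coerce plain matrices on the way into pipeline entry points.
as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) return(x)
  feature_matrix(x)
}

feature_ids <- function(x) colnames(x)

# Columns with (numerically) zero variance, by feature id.
constant_features <- function(x, tol = 0) {
  v <- apply(unclass(x), 2L, stats::var)
  colnames(x)[v <= tol]
}
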