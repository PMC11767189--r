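#' Association matrices over feature pairs
#'
#' `pearson_matrix()`, `spearman_matrix()` and `distance_matrix()` build
#' the M x M matrix of pairwise associations between the columns of a
#' feature matrix. Pearson/Spearman entries are signed in \[-1, 1\];
#' distance-correlation entries lie in \[0, 1\]. The resulting matrix is
#' the input to the nearest-PSD repair and eigen-analysis stages.
#'
#' Constant (zero-variance) features are a hard error here: the
#' distance-correlation "otherwise" branch would silently zero them and
#' corrupt the unit diagonal. Drop them explicitly beforehand.
#'
#' @param X a [feature_matrix()] (or coercible matrix), samples x features.
#' @param engine for `distance_matrix()`: `"fast"` (O(n log n) pairwise
#'   distance covariance) or `"naive"` (O(n^2) double centering).
#'
#' @return a matrix of class `assoc_matrix` with attribute `method` set to
#'   `"pearson"`, `"spearman"` or `"distance"`.
#' @name assoc_matrix
NULL

new_assoc_matrix <- function(entries, method, ids) {
  dimnames(entries) <- list(ids, ids)
  structure(entries, method = method, class = c("assoc_matrix", "matrix", "array"))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d x %d, method = %s\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}

assoc_method <- function(A) attr(A, "method")

check_no_constant <- function(X) {
  bad <- constant_features(X)
  if (length(bad))
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         " (drop before building the association matrix)")
}

#' @rdname assoc_matrix
#' @export
pearson_matrix <- function(X) {
  X <- as_feature_matrix(X)
  check_no_constant(X)
  R <- stats::cor(unclass(X), method = "pearson")
  diag(R) <- 1
  new_assoc_matrix(R, "pearson", feature_ids(X))
}

#' @rdname assoc_matrix
#' @export
spearman_matrix <- function(X) {
  X <- as_feature_matrix(X)
  check_no_constant(X)
  # Pearson correlation of mid-ranks (average ranks on ties)
  R <- stats::cor(apply(unclass(X), 2L, rank, ties.method = "average"),
                  method = "pearson")
  diag(R) <- 1
  new_assoc_matrix(R, "spearman", feature_ids(X))
}

#' Empirical distance covariance, variance and correlation
#'
#' The empirical (biased, V-statistic) distance covariance of two
#' univariate samples: with `a_ij = |x_i - x_j|` and `b_ij = |y_i - y_j|`,
#' double-center each matrix (subtract row and column means, add the grand
#' mean) to get `A`, `B`; then `Vn^2 = mean(A * B)` and
#' `dcov = sqrt(Vn^2)`. `dcor()` normalises by the distance variances and
#' lies in \[0, 1\]; it is 0 whenever either sample is constant.
#'
#' `dcov_naive()` is the direct O(n^2) double-centering estimator;
#' `dcov_fast()` is an exactly equivalent O(n log n) algorithm (sorting
#' plus a Fenwick-tree sweep) suitable for large n.
#'
#' @param x,y numeric vectors of equal length, n >= 2.
#' @return a non-negative scalar (`dcor()` lies in \[0, 1\]).
#' @export
dcov_naive <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  A <- dcenter(abs(outer(x, x, "-")))
  B <- dcenter(abs(outer(y, y, "-")))
  sqrt(max(0, mean(A * B)))
}

dcenter <- function(D) {
  rm <- rowMeans(D)
  D - outer(rm, rep(1, length(rm))) - outer(rep(1, length(rm)), colMeans(D)) +
    mean(D)
}

#' @rdname dcov_naive
#' @export
dvar <- function(x) dcov_naive(x, x)

#' @rdname dcov_naive
#' @export
dcov_fast <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  sqrt(max(0, dcov2_fast_cpp(as.numeric(x), as.numeric(y))))
}

#' @rdname dcov_naive
#' @param engine `"fast"` or `"naive"` distance-covariance backend.
#' @export
dcor <- function(x, y, engine = c("fast", "naive")) {
  engine <- match.arg(engine)
  f <- if (engine == "fast") dcov_fast else dcov_naive
  vx <- f(x, x)
  vy <- f(y, y)
  if (vx * vy <= 0) return(0)
  r2 <- f(x, y)^2 / sqrt(vx^2 * vy^2)
  sqrt(min(max(r2, 0), 1))
}

#' @rdname assoc_matrix
#' @export
distance_matrix <- function(X, engine = c("fast", "naive")) {
  engine <- match.arg(engine)
  X <- as_feature_matrix(X)
  check_no_constant(X)
  f <- if (engine == "fast") dcov_fast else dcov_naive
  M <- ncol(X)
  V <- unclass(X)
  dv <- vapply(seq_len(M), function(j) f(V[, j], V[, j]), numeric(1))
  R <- diag(1, M)
  if (M >= 2L) {
    for (i in seq_len(M - 1L)) {
      xi <- V[, i]
      for (j in (i + 1L):M) {
        r2 <- f(xi, V[, j])^2 / sqrt(dv[i]^2 * dv[j]^2)
        R[i, j] <- R[j, i] <- sqrt(min(max(r2, 0), 1))
      }
    }
  }
  new_assoc_matrix(R, "distance", feature_ids(X))
}
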