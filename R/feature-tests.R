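#' Outcome vectors
#'
#' Wraps an outcome for per-feature testing. Continuous outcomes are
#' numeric; binary outcomes may be factors, characters or two-valued
#' numerics and are encoded with the lexicographically smaller level as
#' group 1 (so t-statistic signs are reproducible).
#'
#' @param values length-n outcome values.
#' @param kind `"continuous"` or `"binary"` (guessed from the values if
#'   omitted: two unique levels and non-numeric, or explicit factors, are
#'   binary).
#' @return an `outcome_vector`: list with `values` and `kind`; binary
#'   outcomes carry a `levels` attribute.
#' @export
outcome_vector <- function(values, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (is.factor(values) || is.character(values) ||
                is.logical(values)) "binary" else "continuous"
  }
  kind <- match.arg(kind, c("continuous", "binary"))
  if (kind == "continuous") {
    values <- as.numeric(values)
    if (anyNA(values)) stop("continuous outcome contains missing values")
  } else {
    values <- as.character(values)
    lev <- sort(unique(values))
    if (length(lev) != 2L)
      stop("binary outcome must have exactly 2 levels, got ", length(lev))
    if (min(table(values)) < 2L)
      stop("each binary outcome level needs at least 2 samples")
    values <- factor(values, levels = lev)
  }
  structure(list(values = values, kind = kind), class = "outcome_vector")
}

as_outcome <- function(y) {
  if (inherits(y, "outcome_vector")) y else outcome_vector(y)
}

# Full-rank design matrix [1, Z]; names rank-deficient columns.
design_matrix <- function(n, Z = NULL) {
  if (is.null(Z) || (is.matrix(Z) && ncol(Z) == 0L)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  Z <- as.matrix(Z)
  if (!is.numeric(Z)) stop("covariates must be numeric (pre-encode factors)")
  if (anyNA(Z)) stop("covariate table contains missing values")
  if (nrow(Z) != n) stop("covariate rows must match the number of samples")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  D <- cbind("(Intercept)" = 1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  D
}

#' Residualize features on covariates
#'
#' Replaces each feature by its least-squares residual from a regression
#' on an intercept plus the covariate columns; the residuals are the
#' covariate-adjusted abundances used by the association-matrix and
#' testing stages. With no covariates this mean-centers each feature.
#'
#' @param X a [feature_matrix()].
#' @param Z numeric n x q covariate matrix (categorical covariates
#'   pre-encoded as indicators), or `NULL`.
#' @return a `feature_matrix` of residuals (same ids).
#' @export
residualize <- function(X, Z = NULL) {
  X <- as_feature_matrix(X)
  D <- design_matrix(nrow(X), Z)
  if (nrow(X) <= ncol(D)) stop("need n > number of design columns")
  R <- qr.resid(qr(D), unclass(X))
  feature_matrix(R, rownames(X), colnames(X))
}

#' Per-feature linear-regression p-values
#'
#' For each feature j fits `y ~ intercept + feature_j (+ covariates)` and
#' returns the two-sided p-value of the t-test on the feature
#' coefficient. Computed via Frisch–Waugh partialling-out: residualize
#' both y and the features on the covariate design once, then the
#' coefficient t-test equals the partial-correlation t-test with
#' `df = n - q - 2`.
#'
#' Features with (numerically) zero variance after adjustment get p = 1
#' with a warning; they are never dropped silently.
#'
#' @param X a [feature_matrix()].
#' @param y continuous outcome ([outcome_vector()] or numeric vector).
#' @param Z optional numeric covariate matrix.
#' @return named numeric vector of p-values with attributes `statistic`
#'   (t values) and `df`.
#' @export
regression_pvalues <- function(X, y, Z = NULL) {
  X <- as_feature_matrix(X)
  y <- as_outcome(y)
  if (y$kind != "continuous")
    stop("regression_pvalues expects a continuous outcome")
  yv <- y$values
  if (length(yv) != nrow(X)) stop("outcome length must match sample count")
  D <- design_matrix(nrow(X), Z)
  df <- nrow(X) - ncol(D) - 1L
  if (df < 1L) stop("need n > q + 2 for the coefficient t-test")
  qrD <- qr(D)
  Xr <- qr.resid(qrD, unclass(X))
  yr <- qr.resid(qrD, yv)
  p <- partial_cor_pvalues(Xr, yr, df)
  structure(stats::setNames(drop(p$p), colnames(X)),
            statistic = stats::setNames(drop(p$t), colnames(X)), df = df)
}

# Two-sided t-test p-values from residualized features vs residualized
# outcome; yr may be a matrix (one column per permutation).
partial_cor_pvalues <- function(Xr, yr, df) {
  sx <- sqrt(colSums(Xr^2))
  zero <- sx <= .Machine$double.eps^0.5 * max(sx, 1)
  if (any(zero))
    warning(sum(zero), " feature(s) have zero variance after adjustment; p = 1")
  yr <- as.matrix(yr)
  sy <- sqrt(colSums(yr^2))
  r <- crossprod(Xr, yr) / outer(sx, sy)
  r[zero, ] <- 0
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tval), df)
  p[zero, ] <- 1
  p <- pmin(p, 1)
  list(p = p, t = tval)  # M x K matrices
}

#' Per-feature Welch two-sample t-test p-values
#'
#' For a binary outcome, tests each feature for a mean difference between
#' the two groups using Welch's unequal-variance t statistic with
#' Welch–Satterthwaite degrees of freedom; two-sided p-values.
#'
#' @param X a [feature_matrix()].
#' @param y binary outcome ([outcome_vector()] or a 2-level vector).
#' @return named numeric vector of p-values with attributes `statistic`
#'   and `df` (per-feature Welch df).
#' @export
welch_t_pvalues <- function(X, y) {
  X <- as_feature_matrix(X)
  y <- as_outcome(y)
  if (y$kind != "binary") stop("welch_t_pvalues expects a binary outcome")
  g <- y$values
  if (length(g) != nrow(X)) stop("outcome length must match sample count")
  if (min(table(g)) < 2L) stop("both groups need at least 2 samples")
  V <- unclass(X)
  i1 <- g == levels(g)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(V[i1, , drop = FALSE])
  m2 <- colMeans(V[!i1, , drop = FALSE])
  v1 <- apply(V[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(V[!i1, , drop = FALSE], 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tval <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               n1 + n2 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tval), df), 1)
  names(p) <- colnames(X)
  structure(p, statistic = stats::setNames(tval, colnames(X)), df = df)
}

#' Significant features at an adjusted threshold
#'
#' Features with `p <= pwer` (boundary inclusive), sorted by ascending
#' p-value.
#'
#' @param p named vector of per-feature p-values.
#' @param threshold an [adjusted_pwer()] result, or a bare pointwise
#'   level.
#' @return list with `count`, `feature_ids` and `p` (the significant
#'   p-values, ascending).
#' @export
significant_features <- function(p, threshold) {
  pwer <- if (inherits(threshold, "adjusted_threshold")) threshold$pwer
          else as.numeric(threshold)
  keep <- which(p <= pwer)
  ord <- keep[order(p[keep])]
  list(count = length(ord),
       feature_ids = if (is.null(names(p))) ord else names(p)[ord],
       p = unname(p[ord]))
}
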