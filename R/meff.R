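#' Eigen-analysis estimators of the effective number of tests
#'
#' Five estimators mapping the eigenvalue spectrum of a features'
#' association matrix to an effective number of statistically independent
#' tests, Meff:
#'
#' * `meff_nyholt()`: `1 + (M - 1) * (1 - var(lambda)/M)` with the sample
#'   variance (M - 1 denominator). M in the identity case, 1 in the
#'   rank-one case.
#' * `meff_liji()`: `sum(f(|lambda_i|))` with
#'   `f(x) = 1(x >= 1) + (x - floor(x))`, splitting each eigenvalue into
#'   an integral "whole test" part and a fractional part.
#' * `meff_gao()`: smallest number of principal components whose
#'   eigenvalues explain at least a fraction `C` (default 99.5%) of the
#'   total variation (inclusive `>=`).
#' * `meff_galwey()`: `(sum(sqrt(lambda)))^2 / sum(lambda)`, with
#'   negative eigenvalues floored to zero upstream.
#' * `meff_peluso()`: `(sum(sqrt(lambda)) / log(lambda1))^2 /
#'   (sum(lambda / lambda1) + lambda1)` with `lambda1` the largest
#'   eigenvalue by default. Unlike the others it is not bounded above by
#'   M, and it is undefined when the largest eigenvalue is <= 1 (log
#'   non-positive) — e.g. on an identity spectrum.
#'
#' All take an [eigen_spectrum()] (or a bare numeric vector of
#' eigenvalues, taken as already floored).
#'
#' @param spectrum an `eigen_spectrum` or numeric vector of eigenvalues.
#' @param C for `meff_gao()`: cumulative proportion threshold.
#' @param lambda1 for `meff_peluso()`: whether the spectral anchor is the
#'   largest (`"max"`, default) or smallest positive (`"min"`) eigenvalue.
#' @return a positive scalar (integer-valued for `meff_gao()`).
#' @name meff_estimators
NULL

#' @rdname meff_estimators
#' @export
meff_nyholt <- function(spectrum) {
  lam <- as_eigen_spectrum(spectrum)$values
  M <- length(lam)
  if (M < 2L) stop("Nyholt's estimator requires M >= 2 eigenvalues")
  1 + (M - 1) * (1 - stats::var(lam) / M)
}

#' @rdname meff_estimators
#' @export
meff_liji <- function(spectrum) {
  lam <- abs(as_eigen_spectrum(spectrum)$values)
  # f is discontinuous at integers; snap eigenvalues within representation
  # error of an integer (exactly degenerate spectra, e.g. duplicated
  # features) so round-off cannot flip the integral part
  snap <- abs(lam - round(lam)) < 1e-9
  lam[snap] <- round(lam[snap])
  sum((lam >= 1) + (lam - floor(lam)))
}

#' @rdname meff_estimators
#' @export
meff_gao <- function(spectrum, C = 0.995) {
  lam <- as_eigen_spectrum(spectrum)$values
  tot <- sum(lam)
  if (tot <= 0) stop("Gao's estimator needs a spectrum with positive total")
  which(cumsum(lam) / tot >= C)[1L]
}

#' @rdname meff_estimators
#' @export
meff_galwey <- function(spectrum) {
  lam <- pmax(as_eigen_spectrum(spectrum)$values, 0)
  tot <- sum(lam)
  if (tot <= 0) stop("Galwey's estimator needs a spectrum with positive total")
  sum(sqrt(lam))^2 / tot
}

#' @rdname meff_estimators
#' @export
meff_peluso <- function(spectrum, lambda1 = c("max", "min")) {
  lambda1 <- match.arg(lambda1)
  lam <- pmax(as_eigen_spectrum(spectrum)$values, 0)
  l1 <- if (lambda1 == "max") max(lam) else min(lam[lam > 0], Inf)
  if (!is.finite(l1) || l1 <= 1)
    stop("peluso undefined for this spectrum (anchor eigenvalue <= 1)")
  (sum(sqrt(lam)) / log(l1))^2 / (sum(lam / l1) + l1)
}

meff_estimator_names <- c("bonferroni", "sidak", "nyholt", "liji", "gao",
                          "galwey", "peluso")

# Dispatch an estimator name over a spectrum; baselines need only M.
meff_from_spectrum <- function(spectrum, estimator, gao_C = 0.995,
                               peluso_lambda1 = "max") {
  spectrum <- as_eigen_spectrum(spectrum)
  switch(estimator,
         bonferroni = ,
         sidak = spectrum$M,
         nyholt = meff_nyholt(spectrum),
         liji = meff_liji(spectrum),
         gao = as.numeric(meff_gao(spectrum, C = gao_C)),
         galwey = meff_galwey(spectrum),
         peluso = meff_peluso(spectrum, lambda1 = peluso_lambda1),
         stop("unknown estimator: ", estimator))
}

new_meff_estimate <- function(estimator, value, corr_method = "none",
                              per_group = NULL) {
  structure(list(estimator = estimator, value = value,
                 corr_method = corr_method, per_group = per_group),
            class = "meff_estimate")
}

#' @export
print.meff_estimate <- function(x, ...) {
  cat(sprintf("<meff_estimate> %s (%s): Meff = %.4f%s\n",
              x$estimator, x$corr_method, x$value,
              if (!is.null(x$per_group))
                sprintf(" over %d groups", length(x$per_group)) else ""))
  invisible(x)
}

#' Bonferroni / Sidak baselines
#'
#' The non-eigen baselines take the effective number of tests to be the
#' full family size M.
#'
#' @param M number of tests.
#' @param estimator `"bonferroni"` or `"sidak"`.
#' @return a `meff_estimate` with `value = M` and `corr_method = "none"`.
#' @export
meff_baseline <- function(M, estimator = c("bonferroni", "sidak")) {
  estimator <- match.arg(estimator)
  if (M < 1) stop("M must be >= 1")
  new_meff_estimate(estimator, as.numeric(M))
}

#' Pointwise error rate for a target family-wise error rate
#'
#' Converts a family-wise error rate `alpha` and an effective number of
#' tests into the per-test (pointwise) significance level: Bonferroni
#' style `alpha / meff`, or Sidak style `1 - (1 - alpha)^(1/meff)`.
#'
#' @param alpha target family-wise error rate in (0, 1).
#' @param meff effective number of tests, >= 1.
#' @param style `"sidak"` or `"bonferroni"`.
#' @return an `adjusted_threshold`: list with `alpha`, `style`, `pwer`.
#' @export
adjusted_pwer <- function(alpha, meff, style = c("sidak", "bonferroni")) {
  style <- match.arg(style)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (inherits(meff, "meff_estimate")) meff <- meff$value
  if (!is.numeric(meff) || meff < 1) stop("meff must be >= 1")
  pwer <- if (style == "bonferroni") alpha / meff
          else 1 - (1 - alpha)^(1 / meff)
  structure(list(alpha = alpha, style = style, pwer = pwer),
            class = "adjusted_threshold")
}

#' @export
print.adjusted_threshold <- function(x, ...) {
  cat(sprintf("<adjusted_threshold> alpha = %g, style = %s, pwer = %.6g\n",
              x$alpha, x$style, x$pwer))
  invisible(x)
}

#' Effective number of tests implied by a pointwise level
#'
#' Inverts the Bonferroni-type relation: `meff = alpha / pwer`. Used to
#' express a permutation-estimated pointwise error rate on the Meff scale.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param pwer pointwise error rate, 0 < pwer <= alpha.
#' @return `alpha / pwer` (>= 1).
#' @export
effective_tests_from_pwer <- function(alpha, pwer) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(pwer) || pwer <= 0 || pwer > alpha)
    stop("pwer must lie in (0, alpha]")
  alpha / pwer
}

# Build the requested association matrix for a feature matrix.
build_assoc <- function(X, corr_method = c("distance", "pearson", "spearman"),
                        engine = "fast") {
  corr_method <- match.arg(corr_method)
  switch(corr_method,
         pearson = pearson_matrix(X),
         spearman = spearman_matrix(X),
         distance = distance_matrix(X, engine = engine))
}

# Correlation submatrix -> repair -> floored spectrum -> estimator value.
meff_one_block <- function(X, estimator, corr_method, engine, floor,
                           gao_C, peluso_lambda1) {
  M <- ncol(X)
  if (M == 1L) {
    if (estimator %in% c("nyholt", "peluso"))
      warning(estimator, " is undefined for a single-feature group; ",
              "contributing 1")
    return(1)
  }
  A <- build_assoc(X, corr_method, engine)
  A <- nearest_psd(A)
  sp <- eigen_spectrum(A, floor = floor)
  meff_from_spectrum(sp, estimator, gao_C = gao_C,
                     peluso_lambda1 = peluso_lambda1)
}

#' Grouped effective number of tests
#'
#' Estimates Meff separately within each feature group (each group's own
#' association submatrix is independently PSD-repaired and floored) and
#' sums the per-group values. Single-feature groups contribute exactly 1;
#' for estimators undefined at M = 1 (Nyholt, Peluso) this is done with a
#' warning.
#'
#' @param X a [feature_matrix()].
#' @param partition a [group_partition()] covering all features.
#' @param corr_method `"distance"`, `"pearson"` or `"spearman"`.
#' @param estimator one of `"nyholt"`, `"liji"`, `"gao"`, `"galwey"`,
#'   `"peluso"`, `"bonferroni"`, `"sidak"`.
#' @param engine distance-covariance backend (distance method only).
#' @param floor eigenvalue flooring threshold.
#' @param gao_C,peluso_lambda1 estimator tuning, see [meff_estimators].
#' @return a `meff_estimate` with the per-group breakdown in `per_group`.
#' @export
meff_grouped <- function(X, partition, corr_method = "distance",
                         estimator = "liji", engine = "fast",
                         floor = 1e-12, gao_C = 0.995,
                         peluso_lambda1 = "max") {
  X <- as_feature_matrix(X)
  partition <- as_group_partition(partition, feature_ids(X))
  per_group <- vapply(levels(partition$groups), function(g) {
    ids <- names(partition$groups)[partition$groups == g]
    meff_one_block(X[, ids, drop = FALSE], estimator, corr_method,
                   engine, floor, gao_C, peluso_lambda1)
  }, numeric(1))
  new_meff_estimate(estimator, sum(per_group),
                    corr_method = if (estimator %in% c("bonferroni", "sidak"))
                      "none" else corr_method,
                    per_group = per_group)
}

#' Distance-correlation-based p-value adjustment pipeline
#'
#' The end-to-end pipeline: association matrix (distance correlation by
#' default; Pearson/Spearman for the classical counterparts) -> nearest
#' positive semidefinite repair -> eigenvalue extraction with flooring ->
#' Meff estimator -> pointwise error rate at the requested family-wise
#' error rate. With a `partition`, Meff is estimated per group and
#' summed. Deterministic given `X`.
#'
#' @inheritParams meff_grouped
#' @param alpha target family-wise error rate.
#' @param style `"sidak"` or `"bonferroni"` adjustment of `alpha` by the
#'   estimated Meff.
#' @param partition optional [group_partition()].
#' @return list with components `meff` (a `meff_estimate`) and
#'   `threshold` (an `adjusted_threshold`).
#' @examples
#' X <- block_correlated(M = 10, block_sizes = c(5, 5), rho = 0.6,
#'                       n = 200, seed = 1)
#' disco_pad(X, estimator = "galwey", alpha = 0.05)
#' @export
disco_pad <- function(X, estimator = "liji", alpha = 0.05,
                      style = c("sidak", "bonferroni"),
                      partition = NULL, corr_method = "distance",
                      engine = "fast", floor = 1e-12, gao_C = 0.995,
                      peluso_lambda1 = "max") {
  style <- match.arg(style)
  X <- as_feature_matrix(X)
  if (!estimator %in% meff_estimator_names)
    stop("unknown estimator: ", estimator)
  if (estimator %in% c("bonferroni", "sidak")) {
    est <- meff_baseline(ncol(X), estimator)
  } else if (!is.null(partition)) {
    est <- meff_grouped(X, partition, corr_method, estimator,
                        engine = engine, floor = floor, gao_C = gao_C,
                        peluso_lambda1 = peluso_lambda1)
  } else {
    v <- meff_one_block(X, estimator, corr_method, engine, floor,
                        gao_C, peluso_lambda1)
    est <- new_meff_estimate(estimator, v, corr_method = corr_method)
  }
  list(meff = est, threshold = adjusted_pwer(alpha, est$value, style))
}
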