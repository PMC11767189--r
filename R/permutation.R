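#' Permutation-based gold standard for the pointwise error rate
#'
#' Estimates the pointwise significance level that attains a target
#' family-wise error rate by permutation: the outcome is shuffled across
#' samples K times (features and covariates stay attached to their
#' samples, so each shuffle is a draw from the global null of no
#' outcome–feature association), all M per-feature p-values are computed
#' for each shuffle, and the minimum p-value is recorded. The
#' floor(alpha * K)-th smallest of these K minima estimates the gold
#' pointwise error rate `alpha_f0`; the implied effective number of tests
#' is `meff0 = alpha / alpha_f0`.
#'
#' All K shuffles are drawn up front from the master `seed` and the
#' p-value computation is vectorised across features and permutations,
#' so results are deterministic and independent of any parallel worker
#' count.
#'
#' @param X a [feature_matrix()].
#' @param y outcome ([outcome_vector()] or coercible vector).
#' @param Z optional numeric covariate matrix; covariate rows never
#'   permute.
#' @param alpha target family-wise error rate.
#' @param K number of permutations; `floor(alpha * K)` must be >= 1, and
#'   K < n/2 triggers a warning.
#' @param seed master RNG seed.
#' @param test `"regression"` (per-feature linear model, covariate
#'   adjusted) or `"welch"` (two-sample t, binary outcomes only). The
#'   default picks regression for continuous and Welch for binary
#'   outcomes.
#' @param ci_level confidence level for the Gaussian-binomial interval on
#'   `alpha_f0` (`NULL` to skip).
#' @return a `permutation_gold`: list with `alpha`, `K`, `q` (sorted K
#'   minimum p-values), `alpha_f0`, `meff0`, `ci`, `seed`, `test`.
#' @examples
#' X <- block_correlated(M = 8, block_sizes = 8, rho = 0, n = 60, seed = 2)
#' y <- null_outcome(60, "continuous", seed = 3)
#' permutation_gold(X, y, alpha = 0.05, K = 200, seed = 4)
#' @export
permutation_gold <- function(X, y, Z = NULL, alpha = 0.05, K = 1000L,
                             seed = 1L, test = NULL, ci_level = 0.95) {
  X <- as_feature_matrix(X)
  y <- as_outcome(y)
  n <- nrow(X)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  K <- as.integer(K)
  idx <- floor(alpha * K)
  if (idx < 1L) stop("K too small for requested alpha (floor(alpha*K) < 1)")
  if (K < n / 2) warning("K < n/2 permutations; estimate may be unstable")
  if (is.null(test)) test <- if (y$kind == "binary") "welch" else "regression"
  test <- match.arg(test, c("regression", "welch"))

  perms <- withr_seed(seed, {
    matrix(replicate(K, sample.int(n)), nrow = n)
  })

  minp <- if (test == "regression") {
    if (y$kind != "continuous")
      stop("regression permutation test needs a continuous outcome")
    min_p_regression(X, y$values, Z, perms)
  } else {
    if (y$kind != "binary")
      stop("welch permutation test needs a binary outcome")
    if (!is.null(Z))
      warning("covariates are ignored by the Welch permutation test")
    min_p_welch(X, y$values, perms)
  }

  q <- sort(minp)
  alpha_f0 <- q[idx]
  structure(list(alpha = alpha, K = K, q = q, alpha_f0 = alpha_f0,
                 meff0 = alpha / alpha_f0,
                 ci = if (is.null(ci_level)) NULL
                      else gold_ci(alpha_f0, K, level = ci_level),
                 seed = seed, test = test),
            class = "permutation_gold")
}

#' @export
print.permutation_gold <- function(x, ...) {
  cat(sprintf(
    "<permutation_gold> K = %d, alpha = %g: alpha_f0 = %.4g, Meff0 = %.2f\n",
    x$K, x$alpha, x$alpha_f0, x$meff0))
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Minimum regression p-value per permutation, vectorised: residualize the
# features once, residualize every permuted outcome column in one QR
# solve, then a single crossprod yields all M x K partial correlations.
min_p_regression <- function(X, yv, Z, perms) {
  n <- nrow(X)
  D <- design_matrix(n, Z)
  df <- n - ncol(D) - 1L
  if (df < 1L) stop("need n > q + 2 for the coefficient t-test")
  qrD <- qr(D)
  Xr <- qr.resid(qrD, unclass(X))
  Yp <- matrix(yv[perms], nrow = n)
  Yr <- qr.resid(qrD, Yp)
  p <- partial_cor_pvalues(Xr, Yr, df)$p
  apply(p, 2L, min)
}

# Minimum Welch p-value per permutation: group moments for every
# permutation via two crossprods with the 0/1 group-indicator matrix.
min_p_welch <- function(X, g, perms) {
  V <- unclass(X)
  n <- nrow(V)
  ind1 <- matrix(as.numeric(g[perms] == levels(g)[1L]), nrow = n)
  n1 <- sum(g == levels(g)[1L]); n2 <- n - n1
  S1 <- crossprod(V, ind1)            # M x K group-1 sums
  Q1 <- crossprod(V^2, ind1)
  St <- colSums(V); Qt <- colSums(V^2)
  m1 <- S1 / n1
  m2 <- (St - S1) / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- ((Qt - Q1) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  tval <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  dfw <- ifelse(se2 > 0,
                se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                n1 + n2 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tval), dfw), 1)
  apply(p, 2L, min)
}

#' Gaussian-binomial confidence interval for the gold pointwise level
#'
#' Normal approximation to the binomial proportion underlying the
#' order-statistic estimate:
#' `alpha_f0 +/- z * sqrt(alpha_f0 (1 - alpha_f0) / K)`, truncated to
#' (0, 1).
#'
#' @param alpha_f0 estimated pointwise level in (0, 1).
#' @param K number of permutations (warning if < 30: approximation poor).
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
gold_ci <- function(alpha_f0, K, level = 0.95) {
  if (alpha_f0 <= 0 || alpha_f0 >= 1) stop("alpha_f0 must lie in (0, 1)")
  if (K < 30) warning("K < 30: Gaussian approximation to the binomial is poor")
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(alpha_f0 * (1 - alpha_f0) / K)
  c(lower = max(alpha_f0 - half, .Machine$double.xmin),
    upper = min(alpha_f0 + half, 1 - .Machine$double.eps))
}
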