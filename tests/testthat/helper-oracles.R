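# Independent oracles, deliberately written on different formula paths
# than the package implementations.

# Distance covariance via the S1 - 2*S2 + S3 expansion (no explicit
# double centering).
oracle_dcov <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  S1 <- sum(a * b) / n^2
  S2 <- sum(rowSums(a) * rowSums(b)) / n^3
  S3 <- sum(a) * sum(b) / n^4
  sqrt(max(0, S1 - 2 * S2 + S3))
}

# Pearson correlation from the raw covariance / sd definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cxy / sqrt(sum((x - mean(x))^2) / (n - 1)) / sqrt(sum((y - mean(y))^2) / (n - 1))
}

# Mid-ranks by counting (independent of base::rank).
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# OLS coefficients by explicit normal equations.
oracle_ols <- function(D, y) solve(t(D) %*% D, t(D) %*% y)

# Random feature matrix helper.
rand_fm <- function(n, M, seed = 1) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(n * M), n, M))
}
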