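test_that("residualize matches normal equations and orthogonality", {
  set.seed(81)
  # intercept only = mean centering
  X <- rand_fm(20, 3, seed = 82)
  R0 <- residualize(X)
  expect_equal(unname(colMeans(R0)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unclass(R0), scale(unclass(X), scale = FALSE),
               ignore_attr = TRUE)

  # residual uncorrelated with covariate
  z <- rnorm(50)
  f <- 2 * z + rnorm(50)
  Xz <- feature_matrix(cbind(f = f, g = rnorm(50)))
  Rz <- residualize(Xz, cbind(z = z))
  expect_lt(abs(cor(Rz[, "f"], z)), 1e-8)

  # closed-form OLS oracle, 1 feature, 2 covariates, n = 10
  Z <- cbind(z1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             z2 = c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0))
  y10 <- c(2.3, 1.1, 4.5, 3.2, 5.9, 4.4, 6.1, 7.0, 8.2, 7.7)
  D <- cbind(1, Z)
  beta <- oracle_ols(D, y10)
  Rf <- residualize(feature_matrix(cbind(f = y10, pad = rnorm(10))), Z)
  expect_equal(unname(Rf[, "f"]), as.numeric(y10 - D %*% beta),
               tolerance = 1e-10)

  expect_error(residualize(Xz, cbind(a = z, b = 2 * z)), "collinear")
})

test_that("regression_pvalues matches the correlation t-test and detects exact fits", {
  set.seed(83)
  X <- rand_fm(60, 4, seed = 84)
  y <- 3 * X[, 2]  # exact linear, no noise
  p <- regression_pvalues(X, y)
  expect_lt(p[2], 1e-12)

  yn <- rnorm(60)
  p2 <- regression_pvalues(X, yn)
  n <- 60
  for (j in 1:4) {
    r <- cor(X[, j], yn)
    t <- abs(r) * sqrt((n - 2) / (1 - r^2))
    expect_equal(unname(p2[j]), 2 * pt(-t, n - 2), tolerance = 1e-12)
  }
  expect_true(all(p2 > 0 & p2 <= 1))

  # zero-variance feature after adjustment -> p = 1 with warning
  z <- rnorm(30)
  Xz <- feature_matrix(cbind(dup = 5 + 2 * z, ok = rnorm(30)))
  expect_warning(pz <- regression_pvalues(Xz, rnorm(30), Z = cbind(z = z)),
                 "zero variance")
  expect_equal(unname(pz["dup"]), 1)
})

test_that("null regression p-values are uniform (KS at 1%)", {
  X <- rand_fm(200, 50, seed = 85)
  y <- null_outcome(200, "continuous", seed = 86)
  p <- regression_pvalues(X, y)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("welch_t_pvalues matches the hand formula and Student collapse", {
  X <- feature_matrix(cbind(m = c(1, 2, 3, 2, 3, 4)),
                      sample_ids = paste0("s", 1:6))
  y <- outcome_vector(rep(c("a", "b"), each = 3))
  p <- welch_t_pvalues(X, y)
  tt <- t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(attr(p, "statistic")["m"]), -1.224745,
               tolerance = 1e-6)
  expect_equal(unname(attr(p, "df")), 4, tolerance = 1e-9)
  expect_equal(unname(p["m"]), tt$p.value, tolerance = 1e-10)

  # identical groups -> t = 0, p = 1
  Xi <- feature_matrix(cbind(m = rep(c(5, 6, 7), 2)))
  pi1 <- welch_t_pvalues(Xi, outcome_vector(rep(c("a", "b"), each = 3)))
  expect_equal(unname(pi1["m"]), 1)

  # balanced equal-variance case equals pooled Student t
  set.seed(87)
  Xb <- rand_fm(40, 6, seed = 88)
  yb <- outcome_vector(rep(c("a", "b"), each = 20))
  pw <- welch_t_pvalues(Xb, yb)
  for (j in 1:6) {
    ps <- t.test(Xb[1:20, j], Xb[21:40, j], var.equal = TRUE)$p.value
    pwv <- t.test(Xb[1:20, j], Xb[21:40, j])$p.value
    expect_equal(unname(pw[j]), pwv, tolerance = 1e-10)
    # df collapse makes Welch ~ Student here
    expect_equal(pwv, ps, tolerance = 5e-2)
  }
})

test_that("significant_features applies the inclusive boundary and sorts", {
  p <- c(a = 0.001, b = 0.02, c = 0.5)
  s <- significant_features(p, adjusted_pwer(0.05, 5, "bonferroni"))  # pwer 0.01
  expect_equal(s$count, 1L)
  expect_equal(s$feature_ids, "a")
  expect_equal(significant_features(p, 1)$count, 3L)
  expect_equal(significant_features(p, 1)$feature_ids, c("a", "b", "c"))
  expect_equal(significant_features(c(x = 0.01), 0.01)$count, 1L)  # boundary in
})

test_that("covariate-adjusted regression agrees with residualized two-step at large n", {
  set.seed(89)
  n <- 500
  z <- rnorm(n)
  X <- feature_matrix(cbind(f1 = rnorm(n) + z, f2 = rnorm(n)))
  y <- 0.5 * z + rnorm(n)
  p_joint <- regression_pvalues(X, y, Z = cbind(z = z))
  Xr <- residualize(X, cbind(z = z))
  yr <- qr.resid(qr(cbind(1, z)), y)
  p_two <- regression_pvalues(Xr, yr)
  # identical up to df correction (q = 1 at n = 500)
  expect_equal(unname(p_joint), unname(p_two), tolerance = 1e-2)
})
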