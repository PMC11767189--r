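test_that("pearson_matrix matches the direct-formula oracle and handles exact cases", {
  x <- c(1, 2, 3)
  X <- feature_matrix(cbind(a = x, b = x + 5, c = rev(x)))
  A <- pearson_matrix(X)
  expect_equal(attr(A, "method"), "pearson")
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], -1)

  X4 <- rand_fm(50, 4, seed = 11)
  A4 <- pearson_matrix(X4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(A4[i, j], oracle_pearson(X4[, i], X4[, j]),
                 tolerance = 1e-12)
  expect_identical(A4, t(A4))
  expect_equal(unname(diag(A4)), rep(1, 4))

  Xc <- feature_matrix(cbind(ok = rnorm(10), flat = rep(2, 10)))
  expect_error(pearson_matrix(Xc), "flat")
})

test_that("spearman_matrix is Pearson on mid-ranks with average ties", {
  x <- 1:4
  X <- feature_matrix(cbind(a = x, b = exp(x), c = -x))
  A <- spearman_matrix(X)
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], -1)

  u <- c(1, 1, 2, 3); v <- c(4, 4, 5, 6)
  At <- spearman_matrix(feature_matrix(cbind(u = u, v = v)))
  expect_equal(At["u", "v"],
               oracle_pearson(oracle_midrank(u), oracle_midrank(v)),
               tolerance = 1e-12)
})

test_that("dcov_naive reproduces hand double-centering and basic laws", {
  expect_equal(dcov_naive(c(0, 1), c(0, 1)), 0.5)
  expect_equal(dvar(c(0, 1)), 0.5)
  expect_equal(dcov_naive(rep(3, 10), rnorm(10)), 0)
  expect_equal(dvar(rep(-1, 5)), 0)

  set.seed(21)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(dcov_naive(x, y), oracle_dcov(x, y), tolerance = 1e-12)
  # translation invariance, linear scaling
  expect_equal(dcov_naive(x + 10, y - 3), dcov_naive(x, y), tolerance = 1e-10)
  expect_equal(dvar(1 - 3 * x), 3 * dvar(x), tolerance = 1e-10)
  expect_error(dcov_naive(1:3, 1:4), "equal length")
  expect_error(dcov_naive(1, 1), "at least 2")
})

test_that("dcor hits its exact cases and affine invariance", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(dcor(x, x), 1)
  expect_equal(dcor(rep(2, 40), y), 0)
  expect_equal(dcor(c(0, 1), c(0, 1)), 1)
  for (eng in c("fast", "naive"))
    expect_equal(dcor(2 - 5 * x, 1 + 0.1 * y, engine = eng), dcor(x, y, engine = eng),
                 tolerance = 1e-10)
})

test_that("dcov_fast equals the naive estimator across sizes and ties", {
  set.seed(31)
  for (n in c(2, 3, 10, 257, 1000)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(dcov_fast(x, y), dcov_naive(x, y),
                 tolerance = 1e-10, label = paste("n =", n))
  }
  # heavy ties, sorted, constant
  xt <- sample(0:2, 200, replace = TRUE)
  yt <- sample(0:2, 200, replace = TRUE)
  expect_equal(dcov_fast(xt, yt), dcov_naive(xt, yt), tolerance = 1e-10)
  expect_equal(dcov_fast(sort(xt), yt), dcov_naive(sort(xt), yt),
               tolerance = 1e-10)
  expect_equal(dcov_fast(rep(1, 50), rnorm(50)), 0)
})

test_that("distance_matrix agrees with per-pair dcor and flags constants", {
  x <- rnorm(60)
  X2 <- feature_matrix(cbind(f1 = x, f2 = 2 * x + 1))
  D2 <- distance_matrix(X2)
  expect_equal(D2["f1", "f2"], 1, tolerance = 1e-10)

  X3 <- rand_fm(60, 3, seed = 41)
  D3 <- distance_matrix(X3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(D3[i, j], dcor(X3[, i], X3[, j], engine = "naive"),
                 tolerance = 1e-10)
  expect_identical(unclass(D3), t(unclass(D3)))
  expect_equal(unname(diag(D3)), rep(1, 3))
  expect_true(all(D3 >= 0 & D3 <= 1))
  expect_equal(attr(D3, "method"), "distance")

  Xc <- feature_matrix(cbind(g = rnorm(10), h = rep(0, 10)))
  expect_error(distance_matrix(Xc), "h")
})

test_that("independent features give small distance correlations; x^2 shows the mechanism", {
  X <- rand_fm(500, 4, seed = 51)
  D <- distance_matrix(X)
  off <- D[upper.tri(D)]
  expect_true(all(off < 0.25))
  # n large enough that the Monte-Carlo error of cor(x, x^2)
  # (sd ~ sqrt(14/n)) sits well inside the 0.1 bound
  set.seed(52)
  x <- rnorm(2000); y <- x^2
  expect_lt(abs(cor(x, y)), 0.1)
  expect_gt(dcor(x, y), 0.3)
})
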