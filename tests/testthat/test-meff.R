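test_that("estimators reproduce their hand-computed spectra", {
  id4 <- rep(1, 4)
  lam <- c(2, 2, 0, 0)
  expect_equal(meff_nyholt(id4), 4)
  expect_equal(meff_nyholt(lam), 3)            # var = 4/3
  expect_equal(meff_nyholt(c(4, 0, 0, 0)), 1)  # var = M

  expect_equal(meff_liji(id4), 4)
  expect_equal(meff_liji(lam), 2)
  expect_equal(meff_liji(c(1.5, 1, 1, 0.5)), 4)

  expect_equal(meff_gao(c(4, 0, 0, 0)), 1L)
  expect_equal(meff_gao(rep(1, 200)), 199L)
  expect_equal(meff_gao(lam), 2L)

  expect_equal(meff_galwey(id4), 4)
  expect_equal(meff_galwey(lam), 2)
  expect_equal(meff_galwey(c(4, 0, 0, 0)), 1)

  expect_equal(meff_peluso(c(4, 0, 0, 0)), (2 / log(4))^2 / 5)
  expect_equal(meff_peluso(lam), (2 * sqrt(2) / log(2))^2 / 4)
  expect_error(meff_peluso(id4), "undefined")
  expect_error(meff_nyholt(1), "M >= 2")
  expect_error(meff_gao(c(0, 0)), "positive total")
})

test_that("estimator monotonicity and bounds over equicorrelation spectra", {
  M <- 12
  prev <- NULL
  for (rho in c(0, 0.2, 0.4, 0.6, 0.8, 0.99)) {
    E <- matrix(rho, M, M); diag(E) <- 1
    sp <- eigen_spectrum(E)
    vals <- c(nyholt = meff_nyholt(sp), liji = meff_liji(sp),
              gao = as.numeric(meff_gao(sp)), galwey = meff_galwey(sp))
    expect_true(all(vals >= 1 - 1e-9 & vals <= M + 1e-9))
    if (!is.null(prev)) expect_true(all(vals <= prev + 1e-9))
    prev <- vals
  }
})

test_that("baselines and threshold adjustment match closed forms", {
  expect_equal(meff_baseline(761, "bonferroni")$value, 761)
  expect_equal(meff_baseline(10, "sidak")$value, 10)
  expect_equal(meff_baseline(761, "sidak")$corr_method, "none")

  expect_equal(adjusted_pwer(0.05, 10, "bonferroni")$pwer, 0.005)
  expect_equal(adjusted_pwer(0.05, 1, "sidak")$pwer, 0.05)
  th <- adjusted_pwer(0.05, 761, "sidak")
  expect_equal(th$pwer, 1 - 0.95^(1 / 761))
  expect_lte(th$pwer, 0.05)
  # Sidak ~ Bonferroni to first order in 1/M
  expect_equal(adjusted_pwer(0.05, 500, "sidak")$pwer, 0.05 / 500,
               tolerance = 2e-3)
  expect_error(adjusted_pwer(1.2, 10), "alpha")
  expect_error(adjusted_pwer(0.05, 0.5), "meff")

  expect_equal(effective_tests_from_pwer(0.05, 0.05), 1)
  expect_equal(effective_tests_from_pwer(0.05, 0.005), 10)
  expect_error(effective_tests_from_pwer(0.05, 0.06), "pwer")
})

test_that("grouped estimation sums per-group values and handles singletons", {
  X <- rand_fm(200, 5, seed = 71)
  one <- group_partition(setNames(rep("all", 5), colnames(X)))
  gl_all <- meff_grouped(X, one, corr_method = "pearson",
                         estimator = "galwey")
  A <- nearest_psd(pearson_matrix(X))
  expect_equal(gl_all$value, meff_galwey(eigen_spectrum(A)),
               tolerance = 1e-10)
  expect_equal(sum(gl_all$per_group), gl_all$value)

  two <- group_partition(setNames(c("a", "a", "a", "b", "b"), colnames(X)))
  gl_two <- meff_grouped(X, two, corr_method = "pearson",
                         estimator = "galwey")
  expect_equal(length(gl_two$per_group), 2L)
  expect_equal(sum(gl_two$per_group), gl_two$value)
  # near-identity blocks: close to 3 + 2
  expect_equal(gl_two$value, 5, tolerance = 0.15)

  sing <- group_partition(setNames(c("a", "a", "a", "a", "solo"),
                                   colnames(X)))
  expect_warning(gs <- meff_grouped(X, sing, corr_method = "pearson",
                                    estimator = "nyholt"), "single-feature")
  expect_equal(unname(gs$per_group[["solo"]]), 1)
})

test_that("paper-style defined cardinalities partition M = 761", {
  card <- c(lipid = 365, xenobiotics = 99, amino_acid = 181,
            carbohydrate = 24, cofactors_vitamins = 25, nucleotide = 32,
            energy = 10, peptide = 25)
  expect_equal(sum(card), 761)
  p <- random_partition(paste0("met", 1:761), card, seed = 72)
  expect_equal(sort(as.integer(p$cardinalities)), sort(unname(card)))
  expect_equal(length(p$groups), 761L)
})

test_that("disco_pad pipeline is deterministic and consistent at large n", {
  X <- block_correlated(M = 20, block_sizes = 20, rho = 0, n = 2000,
                        seed = 73)
  res <- disco_pad(X, estimator = "liji", alpha = 0.05, style = "bonferroni")
  expect_equal(res$meff$value, 20, tolerance = 0.1 * 20)
  expect_equal(res$threshold$pwer, 0.05 / res$meff$value)
  res2 <- disco_pad(X, estimator = "liji", alpha = 0.05,
                    style = "bonferroni")
  expect_identical(res$meff$value, res2$meff$value)

  # duplicated features: exactly orthogonal base columns give the exact
  # spectrum of 2s and 0s -> galwey = M/2
  base <- qr.Q(qr(scale(matrix(rnorm(100 * 20), 100, 20), scale = FALSE)))
  Xd <- feature_matrix(cbind(base, base),
                       feature_ids = paste0("f", 1:40))
  resd <- disco_pad(Xd, estimator = "galwey", corr_method = "pearson")
  expect_equal(resd$meff$value, 20, tolerance = 1e-8)

  # pearson branch equals building blocks bit-for-bit
  rp <- disco_pad(X, estimator = "galwey", corr_method = "pearson")
  sp <- eigen_spectrum(nearest_psd(pearson_matrix(X)))
  expect_identical(rp$meff$value, meff_galwey(sp))
})
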