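#' Feature group partitions
#'
#' A partition assigns every feature to exactly one group; grouped Meff
#' estimation runs per group and sums the contributions.
#'
#' @param groups named vector/factor: names are feature ids, values group
#'   labels.
#' @return a `group_partition`: list with `groups` (named factor) and
#'   `cardinalities`.
#' @export
group_partition <- function(groups) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be named by unique feature ids")
  g <- factor(stats::setNames(as.character(groups), names(groups)))
  names(g) <- names(groups)
  structure(list(groups = g, cardinalities = table(g)),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("<group_partition> %d features in %d groups\n",
              length(x$groups), nlevels(x$groups)))
  invisible(x)
}

as_group_partition <- function(p, ids) {
  if (!inherits(p, "group_partition")) p <- group_partition(p)
  if (!setequal(names(p$groups), ids))
    stop("partition must cover exactly the matrix's features")
  p
}

#' Multivariate Gaussian features from a mean/covariance template
#'
#' Draws n i.i.d. samples from N(mean, cov). This mirrors the template
#' simulation design: estimate a mean vector and covariance matrix from
#' (sub-sampled) real data, then simulate Gaussian feature matrices from
#' them. Marginally indefinite templates are repaired to the nearest PSD
#' matrix with a warning. Sampling uses the symmetric eigen square root,
#' which also handles rank-deficient templates.
#'
#' @param mean length-M mean vector.
#' @param cov M x M symmetric PSD covariance template.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param feature_ids optional feature labels.
#' @return a [feature_matrix()], reproducible from `seed`.
#' @export
mvn_from_template <- function(mean, cov, n, seed = 1L, feature_ids = NULL) {
  M <- length(mean)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == M)) stop("cov must be M x M matching length(mean)")
  cov <- check_square_symmetric(cov, sym_tol = 1e-8)
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    warning("covariance template is indefinite; repairing to nearest PSD")
    e$values <- pmax(e$values, 0)
  }
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  Zm <- withr_seed(seed, matrix(stats::rnorm(n * M), n, M))
  vals <- sweep(Zm %*% rt, 2L, mean, "+")
  feature_matrix(vals, feature_ids = feature_ids)
}

#' Block-equicorrelated Gaussian features
#'
#' Features drawn from a block-diagonal equicorrelation covariance: within
#' a block of size b every pair has correlation `rho`, across blocks
#' features are independent. Each block's population spectrum is known in
#' closed form (`1 + (b-1) rho` once and `1 - rho` with multiplicity
#' b - 1), which makes this the workhorse fixture for validating the
#' eigen pipeline.
#'
#' @param M total number of features (`sum(block_sizes)`).
#' @param block_sizes integer block sizes.
#' @param rho within-block correlation, 0 <= rho < 1.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return a [feature_matrix()].
#' @export
block_correlated <- function(M, block_sizes, rho, n, seed = 1L) {
  if (sum(block_sizes) != M) stop("block sizes must sum to M")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  S <- matrix(0, M, M)
  at <- 0L
  for (b in block_sizes) {
    idx <- at + seq_len(b)
    S[idx, idx] <- rho
    at <- at + b
  }
  diag(S) <- 1
  mvn_from_template(rep(0, M), S, n, seed = seed)
}

#' Nonlinearly dependent feature pairs
#'
#' Each pair is (X, g(X) + eps) with X standard normal and eps Gaussian
#' noise; pairs are mutually independent. For `form = "square"` the
#' population Pearson correlation within a pair is exactly 0 (odd moment
#' of a symmetric law) while the distance correlation is bounded away
#' from 0 — the dependence structure that motivates using distance
#' correlation in the association matrix.
#'
#' @param n_pairs number of (X, g(X)) pairs (so M = 2 * n_pairs).
#' @param n samples, >= 50.
#' @param noise_sd standard deviation of the additive noise.
#' @param form `"square"`, `"abs"` or `"sine"`.
#' @param seed RNG seed.
#' @return a [feature_matrix()] with columns ordered pair by pair.
#' @export
nonlinear_pairs <- function(n_pairs, n, noise_sd = 0.1,
                            form = c("square", "abs", "sine"), seed = 1L) {
  form <- match.arg(form)
  if (n < 50L) stop("need n >= 50")
  g <- switch(form, square = function(x) x^2, abs = abs, sine = sin)
  vals <- withr_seed(seed, {
    out <- matrix(0, n, 2L * n_pairs)
    for (k in seq_len(n_pairs)) {
      x <- stats::rnorm(n)
      out[, 2L * k - 1L] <- x
      out[, 2L * k] <- g(x) + stats::rnorm(n, sd = noise_sd)
    }
    out
  })
  ids <- paste0(rep(paste0("P", seq_len(n_pairs)), each = 2L), c("_x", "_g"))
  feature_matrix(vals, feature_ids = ids)
}

#' Null outcomes
#'
#' Outcomes drawn independently of any feature matrix (use a different
#' seed stream than the features): standard normal for continuous, a
#' balanced two-level shuffle ("a"/"b", floor(n/2) vs ceiling(n/2), or a
#' given prevalence) for binary.
#'
#' @param n number of samples, >= 4.
#' @param kind `"continuous"` or `"binary"`.
#' @param seed RNG seed.
#' @param prevalence for binary outcomes, the fraction of "a" labels
#'   (default balanced).
#' @return an [outcome_vector()].
#' @export
null_outcome <- function(n, kind = c("continuous", "binary"), seed = 1L,
                         prevalence = 0.5) {
  kind <- match.arg(kind)
  if (n < 4L) stop("need n >= 4")
  withr_seed(seed, {
    if (kind == "continuous") {
      outcome_vector(stats::rnorm(n), "continuous")
    } else {
      n1 <- max(2L, min(n - 2L, round(prevalence * n)))
      outcome_vector(sample(rep(c("a", "b"), c(n1, n - n1))), "binary")
    }
  })
}

#' Random feature partition with fixed group cardinalities
#'
#' Uniformly assigns features to groups while preserving the exact group
#' sizes — the "randomly assigned" grouping used to probe whether defined
#' pathway groupings carry real structure.
#'
#' @param feature_ids character vector of feature ids.
#' @param cardinalities integer group sizes summing to the number of
#'   features; names (if any) become group labels.
#' @param seed RNG seed.
#' @return a [group_partition()].
#' @export
random_partition <- function(feature_ids, cardinalities, seed = 1L) {
  M <- length(feature_ids)
  if (sum(cardinalities) != M)
    stop("group cardinalities must sum to the number of features")
  labels <- names(cardinalities)
  if (is.null(labels)) labels <- paste0("G", seq_along(cardinalities))
  assign <- rep(labels, cardinalities)
  perm <- withr_seed(seed, sample.int(M))
  group_partition(stats::setNames(assign[perm], feature_ids))
}
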