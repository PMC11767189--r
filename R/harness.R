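#' Root-mean-squared error against per-repetition gold values
#'
#' @param estimates,golds numeric vectors of equal length.
#' @return `sqrt(mean((estimates - golds)^2))`.
#' @export
rmse <- function(estimates, golds) {
  if (length(estimates) != length(golds))
    stop("estimates and golds must have equal length")
  if (!length(estimates)) stop("need at least one value")
  sqrt(mean((estimates - golds)^2))
}

#' Median and median absolute deviation
#'
#' MAD is unscaled by default (`median(|v - median(v)|)`, no 1.4826
#' normal-consistency factor); pass `mad_scale = 1.4826` for the scaled
#' convention.
#'
#' @param values numeric vector.
#' @param mad_scale multiplier applied to the raw MAD.
#' @return numeric `c(median, mad)`.
#' @export
median_mad <- function(values, mad_scale = 1) {
  if (!length(values)) stop("need at least one value")
  m <- stats::median(values)
  c(median = m, mad = mad_scale * stats::median(abs(values - m)))
}

#' Simulation configuration
#'
#' Describes one benchmarking run of the Meff estimators against
#' per-repetition permutation gold standards.
#'
#' @param generator `"block"`, `"nonlinear"` or `"template"`; the feature
#'   generator used for every repetition.
#' @param generator_args list of arguments for the generator (everything
#'   except `n` and `seed`; see [block_correlated()], [nonlinear_pairs()],
#'   [mvn_from_template()]).
#' @param n samples per repetition.
#' @param reps number of repetitions.
#' @param K permutations per gold standard.
#' @param alpha family-wise error rate.
#' @param estimators estimator names to evaluate.
#' @param corr_methods association-matrix methods to evaluate.
#' @param groupings named list of groupings: `NULL` entries mean
#'   ungrouped; otherwise a [group_partition()] or a vector of group
#'   cardinalities (drawn as a fresh random partition per repetition).
#' @param outcome `"continuous"` or `"binary"` null outcome.
#' @param test permutation test (`NULL`: regression for continuous,
#'   Welch for binary).
#' @param seed master seed; per-repetition seeds are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(generator = "block",
                       generator_args = list(M = 20, block_sizes = 20, rho = 0),
                       n = 100, reps = 10, K = 1000, alpha = 0.05,
                       estimators = c("nyholt", "liji", "gao", "galwey"),
                       corr_methods = c("pearson", "distance"),
                       groupings = list(ungrouped = NULL),
                       outcome = "continuous", test = NULL, seed = 1L) {
  generator <- match.arg(generator, c("block", "nonlinear", "template"))
  stopifnot(alpha > 0, alpha < 1, reps >= 1)
  if (floor(alpha * K) < 1)
    stop("infeasible config: floor(alpha * K) < 1")
  bad <- setdiff(estimators, meff_estimator_names)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  structure(list(generator = generator, generator_args = generator_args,
                 n = n, reps = reps, K = as.integer(K), alpha = alpha,
                 estimators = estimators, corr_methods = corr_methods,
                 groupings = groupings, outcome = outcome, test = test,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_generate <- function(config, seed) {
  args <- config$generator_args
  args$n <- config$n
  args$seed <- seed
  fn <- switch(config$generator,
               block = block_correlated,
               nonlinear = nonlinear_pairs,
               template = mvn_from_template)
  do.call(fn, args)
}

# Spectrum cache: one association matrix + repair per (corr_method,
# grouping block), all estimators evaluated on the shared spectrum.
meff_grid_one_rep <- function(X, config, rep_seed) {
  rows <- list()
  eig_est <- setdiff(config$estimators, c("bonferroni", "sidak"))
  M <- ncol(X)
  for (gname in names(config$groupings)) {
    gspec <- config$groupings[[gname]]
    partition <- if (is.null(gspec)) NULL
      else if (inherits(gspec, "group_partition")) gspec
      else random_partition(feature_ids(X), gspec, seed = rep_seed)
    for (cm in config$corr_methods) {
      blocks <- if (is.null(partition)) list(all = feature_ids(X))
        else split(names(partition$groups), partition$groups)
      spectra <- lapply(blocks, function(ids) {
        if (length(ids) == 1L) return(NULL)  # singleton contributes 1
        A <- nearest_psd(build_assoc(X[, ids, drop = FALSE], cm))
        eigen_spectrum(A)
      })
      for (est in eig_est) {
        vals <- vapply(spectra, function(sp) {
          if (is.null(sp)) return(1)
          tryCatch(meff_from_spectrum(sp, est), error = function(e) NA_real_)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          estimator = est, corr_method = cm, grouping = gname,
          meff = sum(vals), stringsAsFactors = FALSE)
      }
    }
  }
  for (est in intersect(config$estimators, c("bonferroni", "sidak"))) {
    value <- if (est == "bonferroni") M
      else effective_tests_from_pwer(
        config$alpha, adjusted_pwer(config$alpha, M, "sidak")$pwer)
    for (gname in names(config$groupings))
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, corr_method = "none", grouping = gname,
        meff = value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the estimator-vs-gold-standard simulation
#'
#' For each repetition: generate a feature matrix, draw a null outcome,
#' compute the permutation gold standard, then evaluate every requested
#' (estimator x correlation method x grouping) cell. Summaries pair each
#' estimate with its own repetition's gold value (RMSE), and report
#' medians/MADs.
#'
#' Per-repetition seeds are derived deterministically from the master
#' seed, so the report is reproducible and independent of any parallel
#' execution strategy.
#'
#' @param config a [sim_config()].
#' @return a `simulation_report`: list with `estimates` (long
#'   data.frame: rep, estimator, corr_method, grouping, meff), `gold`
#'   (data.frame: rep, meff0, alpha_f0), `summary` (per-cell median, mad,
#'   rmse), and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  est_rows <- vector("list", config$reps)
  gold_rows <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    rs <- (config$seed + 7919L * r) %% .Machine$integer.max
    X <- sim_generate(config, seed = rs)
    y <- null_outcome(config$n, config$outcome, seed = rs + 1L)
    gold <- permutation_gold(X, y, alpha = config$alpha, K = config$K,
                             seed = rs + 2L, test = config$test,
                             ci_level = NULL)
    gold_rows[[r]] <- data.frame(rep = r, meff0 = gold$meff0,
                                 alpha_f0 = gold$alpha_f0)
    g <- meff_grid_one_rep(X, config, rep_seed = rs + 3L)
    g$rep <- r
    est_rows[[r]] <- g
  }
  estimates <- do.call(rbind, est_rows)
  gold <- do.call(rbind, gold_rows)
  key <- interaction(estimates$estimator, estimates$corr_method,
                     estimates$grouping, drop = TRUE)
  summary <- do.call(rbind, lapply(split(estimates, key), function(d) {
    d <- d[order(d$rep), ]
    mm <- median_mad(d$meff)
    data.frame(estimator = d$estimator[1L], corr_method = d$corr_method[1L],
               grouping = d$grouping[1L], median = mm[["median"]],
               mad = mm[["mad"]],
               rmse = rmse(d$meff, gold$meff0[match(d$rep, gold$rep)]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  gm <- median_mad(gold$meff0)
  structure(list(estimates = estimates, gold = gold, summary = summary,
                 gold_median = gm[["median"]], gold_mad = gm[["mad"]],
                 config = config),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf(
    "<simulation_report> %d reps, K = %d, alpha = %g; gold median Meff0 = %.1f (MAD %.1f)\n",
    x$config$reps, x$config$K, x$config$alpha, x$gold_median, x$gold_mad))
  s <- x$summary
  s$cell <- sprintf("%.0f (%.0f)", s$median, s$rmse)
  print(s[, c("estimator", "corr_method", "grouping", "cell")],
        row.names = FALSE)
  invisible(x)
}
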