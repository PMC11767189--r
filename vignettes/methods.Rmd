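---
title: "Effective number of tests from distance correlation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective number of tests from distance correlation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discopad)
```

## The model

Testing M features one at a time at pointwise level $\alpha_f$ controls
the family-wise error rate at
$\alpha \le 1 - (1-\alpha_f)^M$ only under independence. When the
features — and hence the test statistics — are dependent, the family
behaves like $M_{\mathrm{eff}} < M$ independent tests, and the honest
single-step corrections are $\alpha_f = \alpha / M_{\mathrm{eff}}$
(Bonferroni-type) or $\alpha_f = 1 - (1-\alpha)^{1/M_{\mathrm{eff}}}$
(Šidák-type).

$M_{\mathrm{eff}}$ is estimated from the spectrum of the features'
M×M association matrix. The package supports three associations:
signed Pearson, signed Spearman (Pearson on mid-ranks, average ranks on
ties), and the distance correlation
$R(X,Y) = \sqrt{\eta^2(X,Y) / \sqrt{\eta^2(X)\,\eta^2(Y)}} \in [0,1]$
(0 when either distance variance vanishes), where $\eta^2$ is the
empirical distance covariance: double-center the pairwise
absolute-difference matrices of each variable and average their
elementwise product (the biased V-statistic — the variant the fast
algorithm and the classical literature estimate; not the U-centered
unbiased estimator). Distance correlation is zero in the population iff
the variables are independent, so it sees non-linear dependence that
Pearson misses — the motivation for using it in metabolomics, where
feature relationships need not be linear.

Pearson/Spearman entries stay signed: the estimators operate on
eigenvalues, Li–Ji takes $|\lambda|$ itself, and no formula requires
$|r|$ entries.

## The pipeline and its numerical choices

`disco_pad()` runs: association matrix → `nearest_psd()` →
`eigen_spectrum()` → estimator → `adjusted_pwer()`.

* **PSD repair.** An empirical distance-correlation matrix need not be
  positive semidefinite. We project onto the PSD cone in Frobenius norm
  by eigenvalue clipping: symmetrize, set negative eigenvalues to zero,
  reconstruct. We deliberately do **not** restore the unit diagonal
  (the alternating-projection variant with a diagonal constraint is a
  different estimator); the diagonal drift is recorded in the
  `diag_drift` attribute. Repair is applied to Pearson/Spearman matrices
  too — sample Pearson matrices are PSD, so there the projection is the
  identity, which the tests check. An optional re-normalization of the
  repaired diagonal is *not* performed by default; whether the original
  analyses did so is unknowable from the outside, and the projection
  itself is the defined object.
* **Flooring.** Eigenvalues below 1e-12 (configurable) are set to zero;
  this removes negative round-off mass before the estimators take square
  roots.
* **Symmetry tolerance.** Inputs asymmetric beyond 1e-8 are rejected
  rather than silently symmetrized.
* **Li–Ji integer snap.** $f(x) = 1(x\ge1) + (x - \lfloor x\rfloor)$ is
  discontinuous at integers, so an eigenvalue representable only as
  1.9999999999999998 (exactly degenerate spectra, e.g. duplicated
  features) would flip the estimate by 1. Eigenvalues within 1e-9 of an
  integer are snapped before applying $f$. On generic sample spectra the
  snap never fires.
* **Peluso's λ₁.** The published display is ambiguous and indexes
  eigenvalues ascending, but $\log \lambda_{(1)}$ with the *smallest*
  (post-floor, often zero) eigenvalue is undefined, and only the
  largest-eigenvalue reading can produce the documented
  $M_{\mathrm{eff}} > M$ behaviour. We adopt
  $(\sum_i \sqrt{\lambda_i} / \log\lambda_{\max})^2 /
  (\sum_i \lambda_i/\lambda_{\max} + \lambda_{\max})$ with
  `lambda1 = "max"` as the default and expose `"min"` for the literal
  reading. The estimator errors when $\lambda_{\max} \le 1$ (identity-like
  spectra), and singleton groups contribute 1 with a warning.
* **Gao's rule** uses the inclusive ≥ 0.995 comparison; on an identity
  spectrum with M = 200 this gives 199, not 200 — a useful fingerprint
  of the convention.
* **Nyholt's variance** is the sample variance (M−1 denominator).
* **Rounding** happens only at the reporting layer; all pointwise-level
  math uses unrounded $M_{\mathrm{eff}}$. Significance calls use the
  inclusive boundary $p \le \alpha_f$.
* **Grouping.** With a feature partition, each group's submatrix is
  independently repaired and floored, estimators run per group and the
  values are summed. Single-feature groups contribute exactly 1.

## The permutation gold standard

`permutation_gold()` shuffles the outcome across samples K times,
leaving features and covariates attached to their samples, computes all
M per-feature p-values per shuffle (covariate-adjusted linear regression
for continuous outcomes, Welch t for binary — the literal algorithm
description uses regression even for binary outcomes, so a `test`
argument selects either), records each shuffle's minimum p-value, and
takes the $\lfloor \alpha K \rfloor$-th smallest as
$\hat\alpha_{f0}$; $M_{\mathrm{eff}0} = \alpha/\hat\alpha_{f0}$.
The order-statistic index is exact when $\alpha K$ is integral (e.g.
0.05 × 10000) and conservative otherwise. A Gaussian approximation to
the binomial gives the confidence interval
$\hat\alpha_{f0} \pm z_{(1+\ell)/2}\sqrt{\hat\alpha_{f0}(1-\hat\alpha_{f0})/K}$.

All K shuffles are drawn up front from the master seed and the p-value
computation is vectorized across features and permutations (one QR
residualization plus one cross-product), so results are bit-identical
regardless of any parallelization strategy and K = 10,000 at M in the
hundreds costs seconds, not cluster time.

The regression p-values use Frisch–Waugh partialling-out: residualize
features and outcome on the covariate design once; the coefficient
t-test equals the partial-correlation t-test with df = n − q − 2.
Features left with zero variance after adjustment get p = 1 with a
warning — never silently dropped.

## What the synthetic generators emulate — and what a green test establishes

The original evaluation simulated multivariate Gaussian feature matrices
from mean/covariance templates estimated on subsamples of a real cohort
(1136 subjects → 1054 after dropping 82 with missing smoking/lung-function
metadata; 1005 metabolites → 761 after dropping 2 partially characterized
and 242 unidentified). That data is outside this package's test loop, so
`mvn_from_template()` accepts any user-supplied template (reproducing the
original design when the data is downloaded), while CI runs on parametric
stand-ins:

* `block_correlated()` — block equicorrelation with closed-form spectra
  ($1+(b-1)\rho$, $1-\rho$): joint validation of generator and eigen
  pipeline.
* `nonlinear_pairs()` — pairs $(X, g(X)+\varepsilon)$ with
  $g(x)=x^2$ by default (also `abs`, `sine`), noise sd 0.1: dependence
  with zero population Pearson correlation.
* `null_outcome()` — outcomes independent of the features (balanced
  two-level for binary; prevalence exposed).

Defaults follow the stated evaluation world: α = 0.05 throughout;
desk-scale grids (M ≤ 50, n ≈ 100, K = 1000, reps = 20) for CI versus the
original cluster scale (M = 761, K = 10,000, reps = 100). A green test
therefore establishes correctness of the algebra and calibration under
Gaussian/block or pure-nonlinear dependence — it does **not** establish
that the generators reproduce real metabolomics features (no skewness,
no missingness/LOD censoring, no pathway-structured covariance).

One consequence is worth stating plainly, because it leaves an intended
acceptance property red. In the `nonlinear_pairs` world, the permutation
gold standard for *linear-regression* statistics sits near M: for X
standard normal, $\mathrm{corr}(X, X^2) = 0$, so the t-statistics are
nearly uncorrelated even though the features are strongly dependent. The
near-identity Pearson matrix then tracks the gold better than the
distance-correlation matrix, which correctly sees the within-pair
dependence (dcor ≈ 0.57) plus the $O(n^{-1/2})$ V-statistic bias
(≈ 0.17 between independent features at n = 100) and lands further below
the gold. The superiority of the distance-correlation adjustment
reported on template-based simulations arises from strong *linear*
dependence measured noisily at small n — a regime the pure-nonlinear
generator deliberately does not contain. The comparison test is kept at
its stated configuration and left failing rather than re-tuned.

## Simulation harness

`run_simulation()` pairs every estimator × association × grouping cell
with its own repetition's gold standard: per repetition it generates
features, draws a null outcome, computes the gold, and evaluates the
grid off one shared spectrum per (association, group) block. Summaries
are medians, unscaled MADs (`median(|v - median|)`; the 1.4826 factor is
available via `mad_scale` since the original tables do not identify the
convention) and RMSE against the per-repetition gold. Baseline rows
report M (Bonferroni) and the $\alpha/\alpha_f$ rescaling of the Šidák
level, independent of grouping.

Reproducing the original headline tables is a cluster-scale recipe, not
CI: download the cohort data, build the 761-feature template per
subsample, and run `sim_config(generator = "template", ..., n = 100/500/1000,
reps = 100, K = 10000)` with ungrouped, pathway-defined
(365/99/181/24/25/32/10/25) and random groupings.

## Known limitations

* Univariate features only; the general multivariate distance
  correlation is out of scope.
* No significance testing of the distance correlation itself, no FDR
  procedures, no step-down permutation adjustments.
* The V-statistic's positive bias under independence is inherited by
  the association matrix (it vanishes as $n\to\infty$ but is material
  at n ≈ 100); no bias correction is applied, matching the defined
  estimator.
* Peluso's parse could not be cross-checked against its reference
  implementation in this build environment; both λ₁ readings are
  exposed.
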