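---
title: "Model evaluation in genome-wide prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model evaluation in genome-wide prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwpred)
```

## The model and its assumptions

Everything in `gwpred` operates on the no-intercept linear model
`y = X beta + e`, where `X` is an n × p matrix of SNP allele counts
standardized column-wise to mean zero and variance one, and `y` is the
centered phenotype. The intercept is removed by contract rather than
estimated: `standardize()` centers `y` and standardizes `X`, and every
solver assumes that contract. Standardization uses the *population*
(divide-by-n) variance so that `x_j' x_j = n` exactly; this makes the
coordinate-descent denominator `x_j' x_j / n = 1` and the null-model
penalty threshold `lambda_max = max_j |x_j' y| / n` exact identities rather
than approximations. The divide-by-(n−1) convention differs only by a
constant factor and is a one-line change; we record the choice because the
COV/VAR cells of the evaluation report (not the correlation itself) depend
on it, and `decompose(moments = "sample")` exposes the alternative.

By default, standardization statistics are computed over *all* rows and
applied everywhere, which reproduces the single-matrix standardization
described for the benchmark experiment this package replays. That leaks
test-set means and variances into the design; `standardize(stats_from = )`
and `experiment_config(stats_from = "train")` provide the leakage-free
variant, and the pipeline treats the choice as configuration rather than a
hidden constant.

## Three statistics, one disagreement

For hold-out responses `y` and predictions `yhat` the package computes

* test MSE `= mean((y - yhat)^2)`,
* squared Pearson correlation `r2 = cov(y, yhat)^2 / (var(y) var(yhat))`,
* coefficient of determination `R2 = 1 - RSS / TSS`, with `TSS` taken
  around the mean of the supplied test responses.

`R2` is a strictly decreasing transform of MSE for a fixed test set, so
*within one model's penalty path* the MSE-optimal and R2-optimal penalties
coincide — `run_experiment()` asserts this identity on every run. Any
disagreement between criteria is therefore a *cross-model* phenomenon, and
it comes entirely from the affine invariance of `r2`: replacing `yhat` by
`a*yhat + b` changes MSE and R2 but not `r2`. Regularization produces
exactly this kind of distortion — it shrinks `var(yhat)` while `var(y)` is
fixed — so a strongly shrunken model can match a well-calibrated one on
`r2` while losing badly on MSE. `decompose()` reports all six moments so
the mechanism is visible in the output rather than inferred.

Two conventions in the evaluation module were genuinely open and are fixed
as follows. A constant predictor has undefined correlation; `r2_pearson()`
defines it as 0 with a classed warning (the null model at `lambda_max`
predicts a constant by design, and "no predictive correlation" is the
honest score for it). `R2` uses the test-set mean, not the training mean,
because the defining sums run over the same index set; the training-mean
variant would mix split statistics and is intentionally not offered as a
default.

A Cp-style tuning criterion for ridge
(`RSS - n*sigma2_e + 2*sigma2_e*df(lambda)`, with
`df = sum_i d_i/(d_i + lambda)` over the eigenvalues of `X'X`) is included
for completeness. It needs an error-variance estimate, which only an
`n > p` sub-problem can supply — precisely the limitation that makes
hold-out MSE the workhorse in p ≫ n genomics.

## Solvers

**Objective scaling.** The L1 solvers minimize
`(1/(2n))||y - X beta||^2 + lambda * sum_j w_j |beta_j|`. Writing the loss
with the 1/(2n) factor keeps lambda grids comparable across sample sizes
and gives `lambda_max` its closed form; against an unscaled residual sum of
squares the same solution corresponds to `lambda_raw = 2n * lambda`.
`fit_ridge()` keeps the raw normal-equations penalty `(X'X + lambda I)`
because that is how the estimator is universally written; `fit_path()`
converts grid values by `lambda_raw = n * lambda` so one grid serves all
methods.

**Coordinate descent.** Cyclic order, soft-thresholding updates,
convergence when the largest coefficient change in a sweep drops below
`tol = 1e-7`, cap of 10,000 sweeps (a cap hit returns `converged = FALSE`
with a warning, not an error — the partial solution is still usable).
Determinism and auditability were preferred over speed: there are no
active-set heuristics, and the per-sweep objective trace is kept on the
fit so monotonicity is testable. The inner loop is compiled (Rcpp); path
fits are warm-started from the previous penalty, which the test suite
verifies changes nothing beyond tolerance relative to cold starts.

**Ridge.** Solved in closed form: primal `(X'X + lambda I)` when p ≤ n,
dual `beta = X'(XX' + lambda I)^{-1} y` when p > n. Along a path a single
eigendecomposition is shared across all penalties. Because the ridge path
never reaches an exact null model, its default grid is the L1 grid
inflated by 10^3 (`ridge_scale`), mirroring how path software treats
pure-L2 fits; the grid still spans from near-OLS to near-null behaviour.
`fit_gblup()` implements the random-effects view
(`g_hat = G(G + lambda I)^{-1} y`, `G = XX'`), and the test suite asserts
its exact agreement with ridge predictions — the two are one estimator in
two parameterizations, so the implementation treats one as a cross-check
of the other.

**OLS.** Normal equations via QR with a condition-number gate at 1e12;
square full-rank designs are allowed (the identity design is the cleanest
sanity check) but the error-variance estimate additionally requires
`n > p`, since `RSS/(n - p)` has no degrees of freedom otherwise.

**Adaptive weights.** The ALASSO weights derive from the marginal
covariances `c_j = |x_j' y|/n`. A literal penalty weight `w_j = c_j` would
penalize *strong* markers more, inverting the adaptive-LASSO rationale, so
the default is `w_j = 1/(c_j + eps)` with `eps = 1e-8 * max(c_j)` guarding
division; the literal mode is retained (`mode = "literal"`) for
sensitivity analysis, since published descriptions of covariance-based
weighting are ambiguous between the two readings. Ties in model selection
break toward the larger penalty — the more regularized model — so
selections are deterministic and parsimony-leaning.

## What the simulator emulates

The generator targets the summary structure of the QTLMAS2010-style
benchmark: 3,226 individuals in a five-generation pedigree, ~10,000 SNPs,
and a trait built from 37 QTLs — 2 additive majors, 3 maternally imprinted
loci (maternal copy silenced, so only the paternally inherited allele
contributes), 2 epistatic pairs with *no* marginal single-locus effects,
and 28 minors with truncated-normal effects — plus one dominance, one
over-dominance and one under-dominance locus, at narrow-sense
heritability 0.45.

Design choices worth knowing:

* **Pedigree.** 100 founders; the remaining individuals are split as
  evenly as possible across four offspring generations (782/782/781/781 at
  the default total). Random mating, sires from the previous generation's
  males and dams from its females, no selfing by construction.
* **Genotypes.** Founder haplotypes are drawn from a finite ancestral pool
  (20 haplotypes by default) whose per-marker allele frequencies are
  uniform on (0.05, 0.95); shared ancestry plus meiosis with
  Poisson-distributed crossovers (Haldane's no-interference model, 10
  chromosomes × 1 Morgan) induces LD that decays with map distance, which
  the tests verify empirically. Parental origin of every allele is
  tracked, which is what makes imprinting simulable.
* **Effect sizes.** The benchmark description gives QTL counts and classes
  but not effect magnitudes. Minor effects are truncated normal
  (mean 0, sd 1, bounds ±2); additive majors are 3 (three minor-effect
  standard deviations); imprinted, epistatic and dominance-class effects
  are 2 (with the dominance locus at a = 2, d = 1). These are configuration
  defaults chosen so additive variance dominates and the target
  heritability is attainable with positive residual variance — not claims
  about the original data. All are overridable in `qtl_architecture()`.
* **Epistasis with no marginal effects.** The interaction coding (product
  of centered allele counts) is residualized against an intercept and all
  constituent locus codings *on the realized sample*, so each locus's
  marginal linear association with the epistatic component is exactly zero
  in the generated data — not merely zero in Hardy–Weinberg expectation.
* **Heritability calibration.** The residual variance is set on the
  realized sample as `sigma2_e = Var(additive)/h2 - Var(genetic)`, so the
  *expected* realized h² equals the target; the realized value then
  fluctuates only through the residual draw (about ±0.01 at full size).
  Narrow sense is taken seriously: the numerator is the additive component
  alone, while imprinting, epistasis and dominance contribute to the
  denominator.
* **Exactness.** The phenotype is stored as an exact sum of its component
  vectors plus residual, and `realized_h2` is computed from those stored
  components — so decomposition tests assert equality at 1e-12, not
  statistical closeness.

What it does **not** emulate: the original workshop data's actual marker
map and LD structure, selection or non-random mating, sex chromosomes, and
missing genotypes. Passing tests on simulated data therefore demonstrate
that the solvers and metrics behave as the theory predicts under a
realistic genetic architecture; they do not certify performance claims on
any particular real dataset — for that the pipeline accepts the deposited
benchmark files directly.

## Problem sizes and numerical tolerances

The test suite runs the simulator at two scales: desk-scale configurations
(roughly 120–500 individuals × 120–1,000 markers) for structural and
property checks, and the full default size for the heritability
calibration, where 20 replicates give a mean realized h² within ±0.02 of
the 0.45 target. The end-to-end experiment check uses 500 × 1,000 with
20-penalty paths, which keeps a full three-method comparison under a
couple of minutes on one core. Solver oracle tolerances follow the
precision of the underlying arithmetic: closed-form comparisons (ridge
primal vs dual, GBLUP vs ridge, orthonormal soft-thresholding) at 1e-8 to
1e-10, iterative-vs-direct comparisons (coordinate descent vs OLS at
`lambda = 0`) at 1e-6, and exact identities (metric decompositions,
phenotype sums) at 1e-10 to 1e-12.

## Known limitations

* Missing genotypes are rejected, not imputed; inputs must be complete.
* The coordinate-descent solver has no strong-rule screening, so very
  large p is slower than production path solvers, by design (simplicity
  and exact reproducibility were the goals); near-collinear marker blocks
  from tight pedigree LD can require raising `max_sweeps`.
* The Cp-style ridge criterion requires an external error-variance
  estimate and is provided for methodological comparison, not as a
  recommended tuning rule in p > n settings.
* Variance-component estimation (REML/Bayesian) for genomic heritability
  on real data is out of scope; `realized_h2` is a simulator-truth
  quantity, not an estimator.
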