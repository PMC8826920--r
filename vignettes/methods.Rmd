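---
title: "Methods: response-surface and orthogonalized estimation of well-being effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface and orthogonalized estimation of well-being effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

We want the average causal effect of a student's subjective well-being in
one school year on their standardized test score the following year, from
observational cohort data. The adjustment set is large — on the order of 40
raw controls that expand past 100 numeric columns once categorical levels,
an explicit missing level, and missing-value indicators are encoded — and
the controls are strongly inter-correlated (prior achievement, demographic,
family and school-context variables). Three facts shape the design:

1. **OLS and unregularized hierarchical models are unusable** at this
   ratio of columns to rows with collinear controls.
2. **Regularization biases the effect**: a ridge or boosted model that
   shrinks all coefficients also shrinks (or re-routes through correlated
   controls) the treatment coefficient itself.
3. **Linearity of the treatment–outcome relation cannot be assumed a
   priori** — low well-being could plausibly matter more than high.

The package therefore runs a *sensitivity analysis across model families*
rather than committing to a single estimator: a fully linear Bayesian
ridge, a fully nonlinear kernelized Bayesian regression and gradient
boosted trees, and two orthogonalized designs (two-stage ridge, double
machine learning) that are nonlinear in the controls but linear in the
treatment and explicitly protect the treatment coefficient from
regularization.

## Identification and the plugin PD estimator

Under the assumed causal graph — controls (including the prior score and
observed school-context variables) block every backdoor between treatment
T and outcome Y — the interventional mean is

$$
\mathbb{E}[Y \mid \mathrm{do}(T=t)]
  = \int \mathbb{E}[Y \mid X = x, T = t]\, p(x)\, dx
  \;\approx\; \frac{1}{N}\sum_{i=1}^{N} f(x_i, t),
$$

the partial-dependence (PD) curve of any fitted response surface
`f(x, t)`. For a model linear in `t` this collapses to `beta * t + c`
exactly, which the test suite asserts to machine tolerance; for nonlinear
models the curve itself is the effect report. `partial_dependence()`
defaults to 50 grid points spanning the observed treatment range.

## Model families

All five families implement `predict(fit, X, t)`; swapping families changes
no pipeline code.

* **Bayesian ridge** (`fit_bayesian_ridge()`): `y = beta*t + x'gamma + e`
  with a common zero-mean Gaussian prior on the weights. The prior and
  noise precisions maximize the marginal likelihood (type-II ML) by the
  classic fixed-point updates, iterated to relative tolerance `1e-6` with a
  300-iteration cap; non-convergence warns and returns the last iterate
  (a hard error here would discard an entire bootstrap or CV experiment
  over a tolerance event). The intercept is handled by centering and is
  effectively unpenalized. The treatment's posterior SD feeds a
  conservative t-test.
* **Kernelized Bayesian regression** (`fit_kernel_bayesian()`): the same
  model on RBF Nyström features of the joint `(x, t)` row, making the
  surface nonlinear in both arguments.
* **Two-stage kernelized ridge** (`fit_two_stage_ridge()`): stage 1
  ridge-regresses `t` on features of `x`; stage 2 solves a single joint
  penalized least-squares in `(beta, intercept, gamma)` whose penalty
  matrix has a **zero** in the `beta` position (and the intercept), a
  literal implementation of "the treatment coefficient is unregularized".
  At zero penalty and identity features this reproduces OLS exactly
  (Frisch–Waugh), which anchors the standard-error convention below.
* **Gradient boosted trees** (`fit_gradient_boosting()`): stagewise
  least-squares boosting of `rpart` regression trees from the outcome
  mean, step size = learning rate. Written as an explicit staged loop so a
  hand-rolled staged-residual oracle can verify it; the staged training
  RMSE is provably non-increasing for rates in (0, 2].
* **Double machine learning** (`fit_dml()`): school-stratified
  cross-fitting of two nuisance regressions (treatment on controls,
  outcome on controls), then the no-intercept slope of centered outcome
  residuals on centered treatment residuals, with an HC0 sandwich standard
  error. The last stage is a constant effect by default, matching how
  single coefficients are reported; nuisance learners are boosted trees by
  default with a linear-ridge option (used in the recovery experiments on
  linear cohorts, where it is correctly specified and much faster).

### Nyström features

`nystroem_map()` draws `min(300, N)` landmark rows (the paper-gap default;
the choice is testable because with all rows as landmarks the feature map
reproduces exact kernel ridge, an equivalence the suite asserts), computes
the landmark Gram matrix eigendecomposition with a `1e-10` relative
eigenvalue floor, and maps new rows by `K(x, Z) U D^{-1/2}`. The
length-scale defaults to the median pairwise distance when it is not
cross-validated.

## Preprocessing

Rows with any missing well-being subscale or a missing outcome are
excluded; within the remaining rows, continuous controls are mean-imputed
with a paired 0/1 missing indicator, categoricals get one dummy per level
plus an explicit missing level, continuous columns are standardized
(indicators and dummies stay 0/1), and the treatment is standardized to
sample SD 1. The composite well-being index is the first principal
component of the standardized subscales with anxiety and depression
reversed, sign-aligned so higher index = greater well-being (non-negative
correlation with positive affect); running the PCA on standardized inputs
makes the covariance and correlation versions coincide. Sample (n − 1) SDs
are used throughout, consistent with the finite-sample standard errors.

## Inference

For the linear-in-treatment families the standardized effect is
`beta* = beta / s_Y` with `s.e.(beta*) = s.e.(beta) / s_Y`. Degrees of
freedom are `N − D` with `D` counting every design column *including* the
intercept — conservative, because regularization lowers the effective
dimension. The test is a two-sided t-test of `beta / s.e.(beta)`; the
Bayesian ridge substitutes the posterior SD, again conservative under a
shrinkage prior. Intervals are symmetric `±1.96 s.e.` normal intervals:
the construction reproduces published interval endpoints from their
(beta*, s.e.) pairs at four decimals, and at several thousand degrees of
freedom the t and normal quantiles agree to four decimals anyway (a
t-quantile option exists).

Uncertainty for the nonlinear families is visual: rows are resampled with
replacement, imputation re-runs on each resample (single imputation inside
a bootstrap ≈ a simplified multiple imputation, propagating imputation
noise), the model refits with hyperparameters *fixed* at their
pre-selected values, and the PD curve recomputes on a common grid — 50
replicates by default. Replicate rows reuse the full-sample treatment
values so all curves share one treatment scale; replicates that fail on a
degenerate resample are dropped and the achieved count reported. The
resampling unit is the student row (a school-block option exists but is
off by default, since the procedure is row resampling).

## Model selection

Hyperparameters come from a grid search under K-fold cross-validation with
folds *stratified by school*: each school's rows are shuffled and dealt
round-robin, so every fold mirrors the school composition and school-level
controls cannot make out-of-fold errors optimistic. We read
"stratified with respect to schools" as proportional representation, not
leave-school-out (a grouped mode is available behind a flag); K defaults
to 5. Ties break toward stronger regularization, then grid order. CV RMSE
is recorded per cell and reported as missing for DML, whose fitting
procedure does not produce a comparable surface RMSE.

## The synthetic cohort generator

No generative model is published for the real cohort (the data are not
public), so `generate_cohort()` defines one whose *structure* matches the
assumed causal graph and whose *margins* are stylized:

* a per-school effect, observed as the first school-level "climate"
  control column — so the school backdoor is blocked by observed controls;
* latent student ability driving the grade-7 prior score (plus noise);
  the outcome depends on ability only through the prior score, so the
  ability backdoor is blocked by conditioning on prior;
* ~2/3 continuous controls (four of them school-level) and ~1/3
  categoricals with 3–8 levels, so dummy + indicator encoding expands 40
  raw controls toward ~140 columns;
* a latent well-being variable: `confounding_strength` scales its
  dependence on controls and ability, and scales the controls/prior →
  outcome dependence, so `confounding_strength = 0` with zero noise gives
  the exact identity "slope of outcome on latent = true_ate";
* three bounded subscales as affine images of the latent (anxiety 0–2 and
  depression 0–4 loading negatively, positive affect 0–7 positively) plus
  measurement noise `subscale_noise_sd` (default 0.25 of each loading;
  set to 0 in recovery experiments so the PCA index equals the latent and
  the estimand is exactly `true_ate`);
* outcomes on the 0–1000 score scale: prior + mean gain (default 42.52
  points) + confounded baseline + `true_ate` × standardized latent +
  noise (default SD 35 points, giving CV RMSEs in the observed ~39–45
  range); optional smooth quadratic + interaction terms in the baseline
  and/or the treatment map, sharing columns so linear adjustment cannot
  absorb the nonlinear confounding;
* missingness: survey match 0.50 (row-level for all three subscales),
  per-test participation 0.80, control cells MCAR at 0.10 by default
  (a school-keyed MAR mode exists), reproducing the ~0.4 expected
  fraction of rows with both treatment and outcome observed.

Default scale constants (ability 60 points, school 15 points, prior noise
25 points, continuous outcome loadings SD 6 points) put the prior-score SD
near 67 points and the outcome SD near 90–100 points — plausible for
standardized test scales. A closed-form expression for the *naive*
(unadjusted) regression slope, computed from the stored generating
coefficients (`naive_slope_truth()`), is checked against a brute-force
n = 200,000 regression, verifying that the generator's confounding is
calibrated and material (tens of points of omitted-variable bias).

**What passing tests do and do not show.** The generator is
linear-Gaussian with smooth quadratic departures, MCAR-by-default
missingness, and exactly observed backdoor blockers. Real cohorts have
non-Gaussian margins, MNAR missingness, measurement error in the controls,
and possibly unobserved confounding; parameter recovery here demonstrates
the estimators' statistical correctness under the assumed graph, not
robustness to violations of it.

## Experiment sizes and numerical choices

Replicated experiments use sizes chosen to estimate their quantities
stably: parameter recovery at n = 2000 over 200 replicates
(`true_ate = 50` points ≈ 0.5 outcome SDs); regularization-bias ordering
at n = 1000 over 100 replicates with penalty 2000 on the direct ridge and
on the two-stage control weights (stage 1 keeps a moderate penalty of 1 —
the point of the comparison is that the *unpenalized* treatment
coefficient survives heavy control shrinkage); null calibration at
n = 1200 over 100 replicates; the nonlinear CV comparison at n = 600 over
25 replicates with 10 raw controls and the default K = 5 (at K = 3 the
fold-size-200 out-of-fold RMSE noise swamps the ~2-point RMSE gap the
nonlinearity creates). Degenerate inputs error early: zero-variance
vectors in standardization, entirely-missing controls, singular stage-2
systems at zero penalty with collinear encodings (one-hot dummies plus an
intercept need any positive `lambda2`), folds smaller than 5 rows in
cross-fitting.

## Known limitations

* The DML constant-effect last stage does not model effect heterogeneity;
  a covariate-conditioned effect function is a natural extension.
* Bootstrap PD bands are visual uncertainty, not confidence intervals; no
  interval calibration is claimed for the nonlinear families.
* The OLS-style two-stage standard error treats stage-1 residuals as fixed
  regressors; simulation shows it is mildly optimistic (SD ratio ~1.08 at
  n = 2000), offset in practice by the conservative N − D degrees of
  freedom.
* Generator margins are stylized, not calibrated to any real cohort's
  control distribution.
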