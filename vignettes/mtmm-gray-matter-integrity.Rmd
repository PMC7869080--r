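---
title: "Modeling gray-matter integrity with multitrait-multimethod factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gray-matter integrity with multitrait-multimethod factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmmbrain)
```

## The measurement problem

Single imaging measures of a brain region — a voxel-based morphometry (VBM)
volume estimate, a magnetization transfer ratio (MTR), a mean diffusivity
(MD) value — are fallible indicators of the underlying tissue property one
actually cares about, the region's *structural integrity*. Each modality is
sensitive to a different mix of macro- and micro-structural features and each
carries modality-specific nuisance variance. A multitrait–multimethod (MTMM)
confirmatory factor model separates the three sources of variance in a panel
of region-by-modality measures:

* **trait (region) factors** — variance shared across modalities within a
  region; the latent "integrity" of that region;
* **method (modality) factors** — variance shared across regions within a
  modality, orthogonal to the trait factors;
* **residuals** — variance specific to one region in one modality
  (including measurement error).

`mtmmbrain` implements this model family for a design with four regional
integrity factors — prefrontal cortex (PFC; merged medio-orbitofrontal and
dorsolateral indicators, six in total), hippocampus (HC), parahippocampal
gyrus (PHG), precuneus (PRE) — and three correlated method factors (VBM, MT,
MD), plus a latent episodic-memory factor (EM) measured by four behavioral
task scores (verbal learning, face–profession, scene encoding, object
location). The motivating cohort design has 1522 participants with memory
scores and covariates, of whom only 333 underwent imaging; within that
subsample the three modality blocks were observed for 330 (VBM), 197 (MT)
and 274 (MD) participants. All models are therefore estimated by
full-information maximum likelihood (FIML) under a missing-at-random
assumption.

Identification follows the reference-indicator convention: the VBM indicator
anchors each trait factor (loading fixed to 1) and the precuneus indicator
anchors each method factor. MD indicators load negatively on the integrity
factors — higher diffusivity means less dense tissue.

## The model family

| builder | structural layer | df (15–19 observed variables) |
|---|---|---|
| `roi_cfa_spec(roi)` | single region factor | 0 (3 indicators) / 9 (PFC) |
| `mtmm_measurement_spec()` | 4 traits + 3 methods | 64 |
| `mtmm_measurement_spec(TRUE)` | + MD-mofc residual fixed to 0 | 65 |
| `add_age(...)` | age covaries with all 7 factors | 73 |
| `correlational_spec(FALSE/TRUE)` | EM covaries with traits (+ methods) | 120 / 123 |
| `regression_spec()` | EM regressed on the 4 traits | 123 |
| `covariate_adjusted_spec()` | all factors regressed on covariates | — |

The `fix_md_mofc_residual` flag exists because, in the motivating analysis,
the residual variance of the medio-orbitofrontal MD indicator was estimated
at a small negative value (a Heywood case) and was constrained to zero in
all subsequent models; the flag reproduces that decision. Similarly, the
unmerged five-trait variant (`merge_frontal = FALSE`) is available to
demonstrate why the two frontal regions are modeled as one factor: their
estimated correlation exceeds 1 when kept separate.

`correlational_spec(TRUE)` and `regression_spec()` parameterize the same
model space — the structural layer linking EM to the four traits is
saturated either way — so they must agree in log-likelihood and df on any
dataset. The regression form additionally yields the variance in latent
memory explained jointly by the four regions via `r_squared()`,
`R^2 = 1 - psi_EM / Var(EM)`.

## The estimation engine

Starting values are rule-based with one refinement that matters: because
reference loadings are fixed at 1, covariances that involve latent
variables start at half the sample covariance of the variables' reference
indicators (a rough method-of-moments value). With covariances started at
zero instead, the search can settle in degenerate basins where the method
factors collapse.

Models are written in a compact path syntax (`F =~ x1 + x2`, `F ~~ G`,
`y ~ x`, fixes via `0*x`, labels via `lab*x`) and compiled to RAM matrices:
directed paths **A**, symmetric (co)variances **S**, observed-variable
filter **F**, means **M**, with the implied moments
`Sigma = F (I-A)^-1 S (I-A)^-T F'` and `mu = F (I-A)^-1 M`.

**Likelihood.** Rows are grouped by missingness pattern; each pattern
contributes its count, observed-part mean and centered scatter, and the
objective sums the pattern-restricted multivariate-normal deviances. With no
missing cells this reduces exactly to the complete-data likelihood. Means
are *saturated* in every model — one free mean per observed variable — and
are profiled out of the objective in closed form (a generalized
least-squares step per evaluation). Models that need explicit mean
parameters (multigroup intercept equality) carry them in **M** instead.

**Degrees of freedom.** Because means are saturated everywhere (model,
saturated reference, baseline), mean moments cancel against mean parameters
and df is governed by the covariance structure alone:
`p(p+1)/2 - (free covariance-structure parameters)`, summed over groups with
equality-constrained parameters counted once. This convention reproduces the
df ladder 64/73/120/123 above.

**Optimization.** The objective and its analytic gradient are compiled
(RcppArmadillo). The gradient uses the envelope theorem: at the profiled
mean the inner optimization is exact, so the partial derivative holding the
mean fixed is the total derivative. Estimation runs in stages: (1) when
data contain missingness, a fast surrogate fit to the EM-estimated
saturated moments as if complete; (2) dense BFGS on the true objective;
(3) a ridge-guarded Newton polish with the numerical Hessian of the analytic
gradient. A smooth quadratic barrier keeps latent variances (weakly)
positive: MTMM covariance structures admit inadmissible basins with negative
factor variances that fit equally well or better, and an unconstrained
quasi-Newton search will find them. Residual variances of observed
variables remain unbounded so that genuine Heywood cases surface; a fit
flags them, and `fix_heywood = TRUE` refits with the offending variance
pinned to zero — the same admissibility policy the motivating analysis used.
Latent variances that end at the barrier are reported in `fit$boundary`.

Convergence is declared when the optimizer's own criterion is met and the
log-likelihood gradient max-norm is below `1e-5` absolutely or `5e-5`
relative to the deviance magnitude; at cohort-scale deviances (~4e4) an
absolute 1e-5 is below the attainable floating-point resolution of the
objective, which is why the scale-aware alternative exists. Infeasible
parameter values (a non-positive-definite pattern submatrix) return a large
penalty rather than an error, letting line searches back off.

**Reference models and fit.** The saturated model (free means, unrestricted
covariance) is fitted by an EM algorithm for the multivariate normal under
missingness (direct optimization of the free covariance is available as a
cross-check and agrees to 1e-6); the baseline model factorizes into
univariate fits. Then `chi2 = 2(loglik_sat - loglik_model)`,
`CFI = 1 - max(chi2_m - df_m, 0)/max(chi2_b - df_b, chi2_m - df_m, 0)`,
`RMSEA = sqrt(max(chi2_m - df_m, 0)/(df_m * n))` (the `n` convention, with a
switch for `n-1`), and SRMR is the root-mean-square standardized residual
over the lower triangle *including* the diagonal, standardized by the
saturated SDs; mean residuals are excluded because means are saturated.
Standard errors come from the inverse observed information (numerical
Hessian of the compiled objective); standardized-solution SEs use the delta
method with a numerical Jacobian. Inference uses likelihood-ratio tests for
covariances (refitting with the parameter fixed to zero) and Wald z tests
for loadings and variances, two-sided, with no multiplicity correction.

**Measurement invariance.** `invariance_ladder()` fits configural, metric
(loadings equated) and scalar (loadings and intercepts equated, latent means
free in non-reference groups) multigroup models with sequential
likelihood-ratio tests; `median_split()` implements the age-group split with
ties to the lower group.

## The synthetic-data generator

No raw data from the motivating cohort are distributable, so
`default_base2_config()` defines a generating model whose *population*
structure reproduces the study-level quantities: total factor correlations
(e.g. HC–PHG 0.84, PHG–PRE 0.37, VBM–MD −0.53, MT–MD −0.77, EM–HC 0.33),
standardized covariate effects on the factors (e.g. age → HC −0.28,
education → EM 0.29, female advantage on HC 0.69 latent units), descriptive
scales of the covariates (age 70.60 ± 3.84 years, education 14.16 ± 2.89
years, 50.72% female), the implied joint explained variance of latent
memory (about 0.136 from the four trait correlations), and the missingness
design: 333 of 1522 with any imaging, modality blocks kept whole with
probabilities 330/333, 197/333, 274/333, memory scores and covariates
masked cell-wise at their observed rates. The MR subsample is drawn
stratified by sex so that it is 38.44% female against 50.72% overall —
the one marked selectivity in the design — which stays missing-at-random
because selection depends only on observed sex.

Generation is hierarchical: covariates first (sex Bernoulli, age and
education normal), then latent factors as linear functions of centered
covariates plus a multivariate-normal residual whose covariance is the
target total covariance minus the covariate-induced part (positive
definiteness is validated), then indicators from loadings plus residuals.
`population_moments()` returns the implied mean and covariance in closed
form, and the generated sample covariance converges to it elementwise (the
test suite checks n = 200 000 against Monte-Carlo standard errors).

Loadings are configuration values, not study claims: they are chosen so
standardized trait loadings span roughly 0.46–0.86 and method loadings
0.28–0.51 on the analysis scale (mean 5, SD 2), within the wide reported
ranges, and they deliberately *vary across regions*. A degenerate
configuration with loadings constant across regions within modality makes
the model locally unidentified — a uniform shift of all trait covariances
is then exactly absorbed by the method-factor covariance (a rank-one
degeneracy we verified via the moment Jacobian's rank). Region-varying
loadings restore full rank, and are also the realistic case.

One residual is special by design: the medio-orbitofrontal MD indicator's
loadings nearly exhaust its variance, leaving a residual of ~0.02 (0.5% of
the indicator variance). Its estimate therefore hovers at zero in fitted
samples — the Heywood case that motivates the `fix_md_mofc_residual`
constraint — and the constrained model family is (near-)correctly specified
for the generator. Giving that indicator an ordinary residual instead makes
every constrained model misspecified and visibly attenuates the latent
memory–integrity correlations, which is how we settled on this choice.

What the generator does *not* emulate: non-normality (the FIML likelihood
assumes normality and the motivating descriptives are near-normal;
skewness/kurtosis are not reproduced beyond that), any voxel-level or
image-level structure, site or scanner effects, and longitudinal change.
Passing tests therefore certify the statistical machinery under the design's
sample sizes, missingness and effect sizes — not robustness to real-data
pathologies outside that envelope.

Two scales are supported: the default analysis scale (every indicator mean
5, SD 2 — the rescaling the estimation uses to keep optimization
well-conditioned) and `scale = "raw"`, which emits the published raw
descriptive scales (e.g. VBM hippocampus 0.5218 ± 0.0458, MT hippocampus
332.58 ± 31.15) for exercising `rescale_columns()`.

## Preparation operators

* `compute_mtr()` — `(noMT − MT)/noMT`, with an explicit error on zero
  denominators.
* `adjust_for_icv()` — ANCOVA head-size adjustment
  `raw − b (ICV − mean ICV)` with the OLS slope from a reference sample;
  adjusted values are exactly uncorrelated with ICV on that sample.
* `detect_multivariate_outliers()` — squared robust Mahalanobis distances
  against a chi-squared quantile (`p = 1e-4` default, df = number of
  columns, no small-sample F correction), on complete cases only. The
  robust scatter comes from `MASS::cov.rob`; the default estimator is the
  minimum-volume ellipsoid with minimum-covariance-determinant as an
  option — the two agree in the gross-outlier regime this screen targets.
  The pipeline screens the 4 memory scores and the 15 imaging columns as
  two separate blocks, on original scales, *before* rescaling.
* `selectivity_table()` — `(mean_total − mean_sub)/sd_total` per variable,
  with moment-based skewness and plain (non-excess) kurtosis.
* `exclusion_accounting()` — initial n minus erroneous cases minus
  outliers, recorded in the run manifest.

## Numerical and design choices

* **Order of operations**: outlier screening on original scales, then any
  covariate adjustment, then rescaling; rescaling is an estimation aid and
  leaves correlations, chi-square and fit indices invariant (tested).
* **EM reference indicator**: the verbal-learning score; any of the four is
  statistically equivalent.
* **Sex coding**: female = 1, so positive sex effects are female
  advantages.
* **Covariate block**: exogenous and saturated (free variances and
  covariances among covariates).
* **Equivalence testing**: the correlational/regression agreement is
  checked on complete data. Under the full block-missingness design the
  FIML surface is genuinely multimodal near its optimum — the two
  parameterizations can settle in distinct basins about 2e-3 deviance
  apart (we verified by mapping one optimum into the other
  parameterization), a statistically irrelevant but numerically real gap;
  on complete data both reach the same basin and agree to ~1e-11.
* **Problem sizes in the test suite**: moment convergence at n = 200 000;
  parameter recovery at n = 5000; likelihood-ratio calibration with 500
  null replicates at n = 300 (df = 1, 99% binomial band around 0.05);
  attenuation direction with 50 replicates at n = 800. The full suite runs
  in about a minute.

## Known limitations

* Estimation assumes multivariate normality; no robust (sandwich) standard
  errors, categorical estimators, or bootstrap.
* Fits at the design's own size are fragile: with only 197–274 rows
  observed per imaging modality, the maximum of the FIML likelihood can
  genuinely lie at a boundary (a method-factor variance near zero, a
  negative residual variance) for a sizable fraction of simulated samples —
  we verified for such samples that the admissible interior solution has a
  strictly lower likelihood. Fits flag these cases (`fit$boundary`,
  `fit$heywood`), and the refit policy mirrors the constraint the
  motivating analysis adopted. This echoes the convergence difficulties
  reported for the original analysis at the same design.
* Missingness handling is FIML-only; there is no imputation path.
* The invariance ladder implements the standard configural/metric/scalar
  sequence; partial-invariance search is out of scope.
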