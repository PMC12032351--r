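---
title: "Methods: canonical correlation pipelines for brain-behavior association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical correlation pipelines for brain-behavior association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincca)
```

## The problem and the model

Case-control cohort studies of psychiatric and neurological disorders
routinely collect two subject-by-feature tables: multimodal imaging
summaries (regional cortical thickness, task-activation ROIs, resting-state
network metrics) and behavioral phenotypes (clinical scales, daily
functioning, cognitive tests). Canonical correlation analysis asks what
linear pattern in one table covaries maximally with a linear pattern in the
other:

$$ (a_k, b_k) = \arg\max \,\mathrm{cor}(X a, Y b)
   \quad \text{s.t.} \quad \mathrm{cor}(Xa_k, Xa_j) = 0,\; j < k. $$

`cca_fit()` solves this by whitening: with $\Sigma_{xx}, \Sigma_{yy},
\Sigma_{xy}$ the sample (co)variance blocks, the singular values of
$\Sigma_{xx}^{-1/2} \Sigma_{xy} \Sigma_{yy}^{-1/2}$ are the canonical
correlations and the back-transformed singular vectors the weights.
Assumptions are those of classical CCA: linear relations, approximately
multivariate-normal features (checked by `shapiro_wilk_all()` and
`mardia_tests()`), complete data, and $n > p + q$. There is deliberately no
regularized or sparse fallback: when a covariance block is effectively
singular the fit fails loudly rather than silently changing the estimator.

### Numerical choices

- **Whitening** uses a symmetric inverse square root with an eigenvalue
  floor of $10^{-12}\,\mathrm{tr}(\Sigma)$; eigenvalues below the floor
  raise an error naming the offending set. This keeps the solve stable near
  rank deficiency without ever regularizing past it.
- **Sign convention**: each variate pair is flipped so the X-side loading
  of largest magnitude is positive. Signs are otherwise arbitrary in CCA;
  fixing them makes reports reproducible and keeps cross-validation folds
  sign-aligned (otherwise fold SDs are inflated by arbitrary flips).
- **Canonical correlations are clamped to [0, 1]** after the SVD to absorb
  roundoff at the boundaries.

### Wilks' lambda tests

`wilks_tests()` reports, for each $k$, $\Lambda_k = \prod_{i \ge k}
(1 - r_i^2)$ with Rao's F approximation — the convention of mainstream CCA
software — and Bartlett's $\chi^2$ as a secondary column. For univariate
sets Rao's F reduces exactly to $F = r^2(n-2)/(1-r^2)$ on $(1, n-2)$ df,
which the test suite asserts to $10^{-10}$.

## Permutation inference

`permutation_test()` shuffles the subject rows of one set (Y by default;
the choice is exchangeable and a flag exposes the other), refits the CCA,
and records the permuted first canonical correlation. The p-value is the
exact fraction of permutations whose $r_1$ beats the observed one, with no
+1 smoothing; `smoothed = TRUE` switches to the conventional
$(b+1)/(B+1)$ estimator. Because the statistic is already the maximum
correlation over all weight directions, the single test covers the first
pair without per-feature multiplicity correction; higher pairs are judged
by the Wilks sequential tests, since a "beats the observed model"
comparison is defined only for the leading correlation.

Implementation note: shuffling rows of a set leaves its column means and
covariance unchanged, so both sets are whitened once and each permutation
costs one cross-product and one small SVD. This is algebraically identical
to refitting the full CCA per permutation (asserted in the tests) and makes
10,000 permutations at study scale a matter of seconds.

## Cross-validation and the honest fold SD

`cross_validate()` partitions subjects into $k$ near-equal folds by a
seeded shuffle, fits the CCA on each training set (after standardizing with
training-fold means/SDs), projects the held-out subjects with the training
weights and scaling, and records the Pearson correlation of the held-out
first variate pair. Training-only standardization prevents information
leakage; without it the fold correlations are biased toward the in-sample
estimate and the "stability" check is circular.

A consequence worth stating: the across-fold SD of a *held-out* correlation
has a sampling floor of roughly $(1 - \rho^2)/\sqrt{n/k}$ — about 0.05-0.07
for $\rho \approx 0.85$, $n = 250$, $k = 10$ — because each fold correlates
only $n/k$ independent pairs. Reported fold SDs near 0.01 at such sizes are
the signature of a different construction (recording the *training-set*
canonical correlation per fold, whose values are nearly identical because
training sets share $k-2$ folds, and which sit *above* the full-sample
$r_1$). This package deliberately reports the held-out quantity: its mean
tracks the full-sample $r_1$ for genuine signal and collapses toward zero
under the null, which is what a stability diagnostic should do.

## Reference-cohort preprocessing

`preprocess()` runs a fixed, stage-checked chain; each stage validates that
its predecessors ran, so the order cannot be silently rearranged:

1. **Hemisphere averaging** (optional): bilateral cortical features are
   replaced by their arithmetic means (68 thickness features become 34) to
   keep the subject-to-variable ratio workable.
2. **Reference standardization**: z-scores per feature against the
   declared reference group — healthy controls by default, so patient
   scores read as deviation from normative values; the patient sample for
   clinical and functioning scales, whose control variability is too small
   to be a meaningful yardstick. Reference statistics are computed on raw
   (pre-winsorization) values, since standardization precedes clipping.
3. **Winsorization** at ±3 SD (tunable `winsor_limit`), clipping rather
   than dropping outliers.
4. **Reverse-coding** of flagged features so higher always means better;
   an involution, so a second application undoes it.
5. **Group-wise regression imputation**: each missing cell is the OLS
   prediction of its feature from the other features, fitted on
   complete-case rows *of the same group* (expected group differences must
   not bleed across). Predictors are the features observed in that
   subject's row; when they exceed a third of the group size the 5 most
   correlated are used — a deterministic rule that avoids overfitting small
   groups. Observed cells are preserved bit-exactly; this is single
   deterministic imputation, not multiple imputation, so imputation
   uncertainty is not propagated (acceptable at the sub-percent missingness
   the generator defaults emulate).
6. **Covariate residualization**: per feature, a robust linear model
   (Huber M-estimation, tuning constant 1.345, IRLS to relative tolerance
   $10^{-8}$, max 200 iterations — via `MASS::rlm`) of value on age and sex
   is fitted on controls only, and its coefficients are transferred to
   compute residuals for all subjects. Fitting on controls keeps
   disease-related variance out of the covariate model. Sex enters as a 0/1
   indicator (coefficient transfer requires one fixed coding, echoed in the
   report). Age and sex are the residualized covariates; IQ, though often
   matched on, is not regressed out by default — matching already balances
   it and removing it can absorb cognition-related signal.

Diagnostics: per-feature Shapiro-Wilk (delegated to `stats::shapiro.test`;
features above 5000 non-missing values are screened on a deterministic
evenly-spaced subsample, constants reported as non-computable) and Mardia's
multivariate skewness/kurtosis with the ML (1/n) covariance, so the
$p = 1$ case reduces exactly to the univariate moment statistics; skewness
is tested upper-tail $\chi^2$, kurtosis two-sided normal.

## The synthetic-cohort generator

Real patient-level data of this kind are not redistributable, so the
generator is a first-class, tested module that plants known structure:

- **Shared-factor construction**: shared latents $z \sim N(0, I)$;
  the X-side latent is $u_k = z_k$ and the Y-side latent
  $v_k = \rho_k z_k + \sqrt{1-\rho_k^2}\,\varepsilon_k$, so
  $\mathrm{cor}(u_k, v_k) = \rho_k$ *exactly* and — CCA being invariant to
  the invertible loading maps — the planted $\rho$ are exactly the
  population canonical correlations of the noiseless construction. That is
  what makes recovery tests analytic rather than approximate.
- **Default loadings** are square scaled-orthogonal matrices
  ($\sqrt{d}$ scale, drawn once from the spec seed): every feature loads on
  every latent (the redundant, correlated feature blocks typical of
  regional imaging panels and test batteries), the noiseless covariance is
  full rank (so zero-noise constructions remain analyzable), and with the
  default `noise_sd` the attenuation of the planted correlations is
  negligible ($1/\sqrt{1 + \sigma^2/d}$ per side). Latent pairs beyond
  `length(rho)` are planted at correlation zero.
- **Covariates**: ages uniform on 18-65, sex Bernoulli(0.65), identical in
  distribution across groups (a matched design); linear per-feature age/sex
  effects. Controls follow the same feature model with an optional
  patient-only mean shift, so control means/SDs are a valid standardization
  reference.
- **Missingness** is MCAR and confined to the behavioral table (imaging
  pipelines yield complete summary tables; behavioral batteries are where
  cells go missing). The study-schema default rate is 0.8%.
- **Outliers** are planted at 5-8 column SDs with random sign in both
  tables, so ±3 SD winsorization provably clips every one.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: non-Gaussian score distributions
(floor/ceiling effects in rating scales), informative (non-MCAR)
missingness, site/scanner effects, and any realistic spatial structure in
images. The RSN generator likewise produces linear mixtures of synthetic
spatial maps with Gaussian noise, not fMRI.

The study-schema scenario (`generate_study_cohort()`) fixes the cohort
shape at 167 patients + 46 controls, 56 imaging features (34 structural,
12 task, 10 resting) and 23 behavioral features (6 clinical, 2 functioning,
15 cognitive), one planted pair at $\rho = 0.84$, unit feature noise,
0.8% behavioral missingness and 0.5% outlier cells.

## Resting-state network metrics

`dual_regression()` implements the two-stage least squares: (1) each
timepoint's voxel vector regressed on all group maps simultaneously —
multiple regression, so each component's time series is estimated while
controlling for the others, which matters whenever maps overlap; (2) each
voxel's time course regressed on the variance-normalized time series,
giving parameter-estimate (PE) maps on a scale comparable across subjects.
Unit-variance normalization of the step-1 series is the common convention
and is what makes "integrity" (mean PE over a network's voxels,
`network_integrity()`) interpretable across subjects. A network's voxel set
is taken as the voxels where its group map exceeds `mask_z` (default 3.0),
exposed in the configuration since "the network's voxels" is otherwise
undefined for continuous maps. Segregation is
$z = \operatorname{atanh}(r)$ of each pair of step-1 time series
(`network_segregation()`); perfectly correlated series are capped at
$\operatorname{atanh}(1 - 10^{-15})$ with a warning rather than returned as
infinite. Subjects are excluded when mean framewise displacement strictly
exceeds 0.2 mm. Group ICA itself and template matching are upstream of this
package: group maps are an input. Segregation uses plain Pearson
correlations between time series, not partial correlations.

## Pipeline topology

`run_analysis()` preprocesses once and reuses the resulting matrices for
the global CCA (all imaging features) and each modular CCA (one imaging
modality at a time, all behavioral features) — subsetting columns, not
re-preprocessing, so the models are strictly comparable. Only patients
enter the CCAs; controls serve as the standardization and residualization
reference. The four model p-values are reported uncorrected, with an
optional Bonferroni flag (off by default) for users who want
across-model correction. Every random draw (permutations, folds) derives
from the mandatory config seed, and a rerun with the same config reproduces
every output byte.

## Problem sizes in the test suite

The suite validates contracts at sizes chosen to keep the whole run around
half a minute while leaving Monte-Carlo margins: oracle equivalence at
$n \le 40$, $p, q \le 3$ (plus a 1°-grid brute-force maximization at
$p = q = 2$); recovery of $\rho = (0.8, 0.4)$ at $n = 500$, $p = 10$,
$q = 8$ over 50 seeds; permutation calibration over 200 null replicates of
$n = 100$ with 500 permutations each; and the full study-schema pipeline
end-to-end with 1000 permutations. Checks of stochastic quantities assert
averages over replicates rather than single draws, keeping them well inside
sampling noise without widening the scientific tolerance.

## Known limitations

- Classical CCA only: no sparse/regularized variants, no more than
  $\min(p, q)$ pairs, no confidence intervals on loadings.
- Permutation p is defined for the first pair; later pairs rely on the
  parametric Wilks approximation.
- Single deterministic imputation; no uncertainty propagation.
- Covariate adjustment is linear in age; no site harmonization.
- The RSN module consumes delimited matrices; neuroimaging volume formats
  are an adapter concern, not core.
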