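# braincca

Multivariate brain–behavior association analysis for case–control cohort
studies: canonical correlation analysis (CCA) between a multimodal imaging
feature set and a behavioral feature set, wrapped in the reference-cohort
preprocessing, permutation inference, and cross-validation machinery such
studies need — plus a synthetic-cohort generator with planted canonical
structure so every stage can be validated against known ground truth.

## Who this is for

Studies that collect, per subject, a table of imaging-derived features
(regional cortical thickness, task-activation ROIs, resting-state network
metrics) and a table of behavioral features (clinical scales, daily
functioning, cognitive test scores) in a patient group, together with a
matched healthy-control (HC) sample, and ask: *what pattern of brain
features covaries with what pattern of behavior?*

## The model

CCA finds paired weight vectors $a_k, b_k$ maximizing the Pearson
correlation of the canonical variates $u_k = X a_k$, $v_k = Y b_k$:

$$r_k = \max_{a, b} \,\mathrm{cor}(X a, Y b), \qquad
  \mathrm{cor}(u_j, u_k) = 0 \;\; (j \ne k),$$

solved by singular value decomposition of
$\Sigma_{xx}^{-1/2}\,\Sigma_{xy}\,\Sigma_{yy}^{-1/2}$. Interpretation uses
**loadings** (correlation of each feature with its own set's variate) and
**cross-loadings** (correlation with the other set's variate), flagged as
substantial when $|r| > 0.3$. Inference:

- **Wilks' lambda** sequential tests, $\Lambda_k = \prod_{i\ge k}(1-r_i^2)$,
  with Rao's F approximation;
- a **permutation test** of $r_1$ (subject rows of one set shuffled, CCA
  refitted; p = fraction of permutations beating the observed $r_1$);
- **k-fold cross-validation**: weights fitted on training folds, held-out
  subjects projected, the test-fold variate correlation recorded per fold.

Preprocessing follows the reference-cohort convention: z-standardization
against the HC sample (patient-referenced for clinical/functioning scales),
winsorization at ±3 SD, reverse-coding so higher = better, group-wise
linear-regression imputation, and residualization of age and sex with
robust (Huber) models fitted on HC only and transferred to patients.
Resting-state inputs are summarized by dual regression of group ICA maps
into per-subject network **integrity** (mean PE per network) and
**segregation** (Fisher-z between-network time-series correlations), with
subjects excluded at mean framewise displacement > 0.2 mm.

## Worked example

```r
library(braincca)

spec <- cca_spec(n_patients = 120, n_controls = 40, p = 8, q = 5,
                 rho = c(0.7, 0.3), noise_sd = 0.5, age_beta = 0.02,
                 missing_rate = 0.01, seed = 42)
cohort <- generate_cohort(spec)
report <- run_analysis(cohort, config = list(seed = 42, n_perm = 2000, k_folds = 10))
report
```

```
Brain-behavior CCA analysis report
  global       r1 = 0.66, permutation p = 0, CV mean r = 0.52 (SD 0.15), p = 8, q = 5
  structural   r1 = 0.66, permutation p = 0, CV mean r = 0.49 (SD 0.23), p = 8, q = 5
```

The planted first canonical correlation was 0.70; the in-sample estimate
0.66 reflects the mild attenuation from feature noise, the permutation p of
0 (no permutation among 2000 beat it) confirms the association, and the CV
mean of 0.52 shows the honest held-out correlation — lower than in-sample,
as expected when p + q = 13 weights are estimated from 120 subjects.

```r
summary(report$models$global$fit)
```

```
Canonical correlation analysis
  n = 120 subjects, p = 8 x-features, q = 5 y-features
  canonical correlations: 0.659, 0.469, 0.377, 0.230, 0.134

Sequential Wilks' lambda tests (Rao's F):
 pair lambda     F df1 df2  p_value
    1  0.352 3.170  40 469 2.00e-09
    2  0.623 1.979  28 394 2.55e-03
    3  0.798 1.452  18 314 1.06e-01
    4  0.930 0.837  10 226 5.94e-01
    5  0.982 0.525   4 115 7.17e-01

First pair: 7 features with |loading| > 0.30
```

The Wilks table reads sequentially: pair 1 tests all five correlations,
pair 2 tests what remains after removing the first, and so on — here the
planted two-pair structure (0.7, 0.3) is exactly what survives.

`plot(report$models$global$fit)` draws the first variate-pair scatter, and
`write_report(report, "out/")` emits a JSON report, loading/cross-loading
TSVs, and a plain-text summary with substantial cross-loadings ranked by
magnitude.

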