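# dosiomics

Predicting radiation pneumonitis (RP) from 3D radiotherapy dose
distributions. RP is an inflammatory lung toxicity of thoracic irradiation
(graded 0-4, binarized here at grade >= 1). Classical risk models summarize
the lung dose through dose-volume histogram (DVH) metrics; this package
implements, end to end, the *dosiomics* alternative - radiomics-style
texture analysis of the 3D dose field inside the lung - together with
voxel-wise correction of fractionated dose to the equivalent dose in 2 Gy
fractions (EQD2), so that DVH and dosiomic feature sets can be compared with
and without accounting for fraction-size effects. It is aimed at medical
physics and outcomes-modeling researchers.

## What it computes

**EQD2 accumulation.** With per-voxel fraction doses $d_i$ and
linear-quadratic tissue parameter $\alpha/\beta$ (3 Gy for lung),

$$\mathrm{EQD2} = \sum_i \frac{d_i + d_i^2/(\alpha/\beta)}{1 + 2/(\alpha/\beta)},$$

accumulated fraction by fraction per voxel. When beam arrangements vary
between fractions the per-voxel fraction size varies, and EQD2 diverges from
the plain summed dose - the central contrast the pipeline quantifies.

**Features** (per dose variant, physical sum and EQD2, from the lung ROI at
1.5 mm isotropic resolution): 16 DVH features (V5-V70 in 5 Gy steps, mean
lung dose, gEUD with n = 0.99) and 93 dosiomic features (18 first-order
statistics and 75 texture features over GLCM, GLRLM, GLSZM, NGTDM and GLDM
matrices after fixed 1 Gy / 100-level discretization), implemented from
scratch with brute-force-verified matrix accumulators.

**Modeling.** Four feature groups (DVH, DVHEQD2, DO, DOEQD2). Dosiomic
groups are redundancy-filtered (greedy, |Spearman rho| > 0.8). Each group is
modeled over repeated random 80/20 splits: training-set min-max
normalization, minority oversampling, L1-regularized logistic regression
(glmnet) with the penalty tuned by repeated inner 5-fold cross-validation
maximizing mean AUC. Groups share split partitions, so comparisons are
paired: AUC summaries, per-feature selection frequencies, odds ratios mapped
back to raw feature scale, paired Z-tests (with Nadeau-Bengio variance
correction for resampled splits) and mean ROC curves.

**Synthetic cohorts.** No patient data ship with the package.
`simulateCohort()` generates fractionated dose grids (Gaussian-profile
beams through a mediastinal target, per-fraction beam re-weighting), a
two-lobed lung mask, and RP labels planted through a logistic model on
realized V40 and a scale-free texture (busyness) covariate - so every
pipeline stage is testable, including signal-recovery experiments.

## Worked example

```r
library(dosiomics)

# the EQD2 correction at a glance: 2 Gy is the fixed point
eqd2Scalar(c(1.8, 2, 3), lqParams(alphaBeta = 3))
#> [1] 1.728 2.000 3.600

# a small synthetic cohort, end to end
cfg <- runConfig(
  cohort   = deskCohortSpec(nPatients = 60, seed = 2),
  modeling = deskModelingConfig(seed = 2))
res <- runAll(cfg)

sapply(res$summaries, `[[`, "aucMean")
#>       DVH   DVHEQD2        DO    DOEQD2
#> 0.7464533 0.6999390 0.7510437 0.7576816

# paired comparison of the dosiomic vs the DVH group
cmp <- compareGroups(res$results$DO, res$results$DVH)
round(c(z = cmp$statistic, p = cmp$pValue), 4)
#>      z      p
#> 0.0596 0.9524

# most frequently selected features over the 200 splits
head(sort(res$summaries$DVH$selectionFrequency, decreasing = TRUE), 4)
#>    V5   V40   V45   V25
#> 0.925 0.900 0.610 0.555
head(sort(res$summaries$DO$selectionFrequency, decreasing = TRUE), 3)
#>             glrlm_RunEntropy             glcm_Correlation
#>                        0.955                        0.870
#> glszm_GrayLevelNonUniformity
#>                        0.395
```

This cohort plants both default effects (risk-increasing V40,
risk-decreasing texture busyness). The DVH group recovers the mid-dose
signal - V40 is selected in 90% of the 200 splits - while the dosiomic group
matches its discrimination (AUC 0.75) through texture features (run entropy,
co-occurrence correlation) that track the planted texture driver. The paired
z-statistic compares the two groups across the same 200 splits with a
variance correction for split overlap; here the groups genuinely tie.
Cohorts with a *single* planted effect separate the groups sharply - those
recovery experiments run in `tests/testthat/test-acceptance.R`.

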