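---
title: "Dosiomic modeling of radiation pneumonitis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosiomic modeling of radiation pneumonitis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dosiomics)
```

## The problem

Radiation pneumonitis (RP) is an inflammatory lung toxicity of thoracic
radiotherapy, graded 0-4 and binarized here at grade >= 1. Classical
predictors summarize the planned dose to the lungs through the dose-volume
histogram (DVH): the relative lung volume receiving at least x Gy (Vx), the
mean lung dose (MLD) and the generalized equivalent uniform dose (gEUD).
DVH metrics discard all spatial structure. *Dosiomics* instead treats the 3D
dose distribution as an image and extracts radiomics-style texture features
from the lung region of interest, asking whether the spatial pattern of dose
carries predictive information beyond the DVH.

A second question concerns fractionation. A treatment is delivered in many
fractions, and with 3D-conformal techniques the beam arrangement can change
between fractions, so the *per-voxel* fraction size varies even when the
prescription point receives a constant dose per fraction. Under the
linear-quadratic cell-survival model, biological effect depends on fraction
size; the equivalent dose in 2 Gy fractions accumulated over fractions $i$
with per-voxel fraction dose $d_i$ is

$$\mathrm{EQD2} = \sum_i \frac{d_i + d_i^2/(\alpha/\beta)}
                              {1 + 2/(\alpha/\beta)},$$

applied voxel-wise with $\alpha/\beta = 3$ Gy (the conventional late-lung
value; `lqParams(alphaBeta = 3)`). Two properties matter and are enforced by
tests: 2 Gy per fraction is the fixed point of the correction, and the
correction must be accumulated fraction by fraction - computing it from the
summed physical dose is wrong precisely when per-voxel fraction size varies,
which is the situation the pipeline is designed to quantify. The package
therefore models four feature groups: DVH and dosiomic (DO) features, each
extracted from the uncorrected physical sum and from the EQD2-corrected
accumulation (DVHEQD2, DOEQD2).

## Pipeline

1. **Ingestion and geometry** (`readVolume`, `resampleToIso`,
   `harmonizeSeries`): volumes live on regular grids with (x, y, z) array
   order and world coordinate `origin + (index - 1) * spacing` in mm. All
   grids are resampled to 1.5 mm isotropic resolution before feature
   extraction - trilinear interpolation for dose, nearest neighbour for
   masks (standard practice for label volumes; the choice is visible in the
   mask staying exactly binary). Fractions on mismatched grids are
   harmonized to the first fraction's geometry.
2. **Accumulation** (`sumFractions`, `eqd2Accumulate`).
3. **DVH features** (`extractDvhFeatures`): V5-V70 in 5 Gy steps (stored as
   fractions in [0, 1]; percent is a reporting concern), MLD, and gEUD with
   n = 0.99. Sixteen features per dose variant.
4. **Dosiomic features** (`extractDosiomicFeatures`): 18 first-order
   statistics plus 75 texture features over five families - GLCM (24),
   GLRLM (16), GLSZM (16), NGTDM (5), GLDM (14); 93 per dose variant.
5. **Modeling** (`spearmanRedundancyFilter`, `runGroup`): redundancy
   filtering of the dosiomic groups, then 1000 random 80/20 splits with
   minority oversampling, nested cross-validated LASSO-logistic fitting and
   test-AUC evaluation.
6. **Evaluation** (`summarizeGroup`, `compareGroups`, `rocCurveMean`):
   AUC summaries, per-feature selection frequencies, odds ratios on the raw
   feature scale, paired Z-tests between groups and vertically averaged ROC
   curves.

## Feature dictionary

Discretization uses fixed 1 Gy bins anchored at 0 Gy - level
$k$ covers $[k-1, k)$ Gy - clamped to at most 100 levels, so levels are
physically meaningful dose bands comparable across patients. The anchoring
convention (at 0 rather than at the in-mask minimum) is a deliberate choice;
it is exposed in `discretizationSpec()` together with the bin width and
level cap.

Throughout, $P$ is the normalized matrix of the family, $i$ indexes gray
level (the actual dose-band index, not a re-indexed rank), $N_p$ the number
of in-mask voxels. Features whose denominator vanishes on (near-)constant
volumes - GLCM correlation and MCC, NGTDM coarseness, busyness and strength,
first-order skewness and kurtosis - return 0 with a warning; this
deterministic convention keeps constant inputs finite and is asserted by
tests.

**First order** (over continuous in-mask dose; entropy and uniformity over
the discretized histogram $p$): energy $\sum x^2$ and total energy
(voxel volume $\times$ energy), entropy $-\sum p \log_2 p$, minimum, 10th
and 90th percentiles and median (linear interpolation between order
statistics), maximum, mean, interquartile range, range, mean absolute
deviation, robust MAD (restricted to values within the 10th-90th percentile
band), RMS, skewness $m_3/m_2^{3/2}$, kurtosis $m_4/m_2^2$ (not
excess-corrected), population variance, uniformity $\sum p^2$.

**GLCM**: symmetrized co-occurrence over the 13 unique offsets at Chebyshev
distance 1; features are computed per direction and averaged (matrices are
not merged). With $p_x$ the marginal, $\mu = \sum i\, p_x(i)$,
$p_{x+y}$/$p_{x-y}$ the diagonal-band sums: autocorrelation
$\sum_{ij} ij P$, cluster prominence/shade/tendency
$\sum_{ij} (i+j-2\mu)^{4,3,2} P$, contrast $\sum (i-j)^2 P$, correlation
$(\sum_{ij} ijP - \mu^2)/\sigma^2$, difference average/entropy/variance on
$p_{x-y}$, Id $\sum_k p_{x-y}(k)/(1+k)$, Idm ($1+k^2$), Idn and Idmn
(arguments scaled by $N_g$ and $N_g^2$), inverse variance
$\sum_{k\ge 1} p_{x-y}(k)/k^2$, joint average, joint energy $\sum P^2$,
joint entropy, maximum probability, MCC (square root of the second-largest
eigenvalue of $Q(i,j) = \sum_k P(i,k)P(j,k)/(p_x(i)p_x(k))$), sum average
and sum entropy on $p_{x+y}$, sum of squares
$\sum (i-\mu)^2 P$, and the two information measures of correlation built
from the joint and marginal entropies.

**GLRLM**: maximal constant-level runs along each of the 13 directions
(out-of-mask voxels break runs), per-direction features averaged. With run
counts $P(i, r)$, $N_r = \sum P$: short/long-run emphasis weight by
$1/r^2$ and $r^2$; low/high-gray-level emphasis by $1/i^2$ and $i^2$; the
four combined variants multiply the weights; gray-level and run-length
non-uniformity are $\sum_i (\sum_r P)^2/N_r$ and
$\sum_r (\sum_i P)^2/N_r$ with normalized variants dividing by $N_r^2$; run
percentage is $N_r/N_p$; plus gray-level variance, run variance and run
entropy on $P/N_r$.

**GLSZM**: identical formula template applied to 26-connected constant-level
zones (level, zone size), a single matrix with no direction dependence.

**NGTDM**: for each occupied level $i$, $n_i$ counts in-mask voxels of level
$i$ with at least one in-mask 26-neighbour and
$s_i = \sum |i - \bar{A}|$ over those voxels, where $\bar{A}$ is the mean
level of the voxel's in-mask neighbours. With $p_i = n_i/N_v$: coarseness
$1/\sum p_i s_i$, contrast
$\big[\frac{1}{N_{gp}(N_{gp}-1)}\sum_{ij} p_i p_j (i-j)^2\big]
 \big[\frac{1}{N_v}\sum s_i\big]$, busyness
$\sum p_i s_i / \sum_{ij} |i p_i - j p_j|$, complexity
$\frac{1}{N_v}\sum_{ij} |i-j| (p_i s_i + p_j s_j)/(p_i + p_j)$, strength
$\sum_{ij} (p_i + p_j)(i-j)^2 / \sum s_i$.

**GLDM**: the dependence of a voxel is the number of its in-mask
26-neighbours whose level differs by at most $\alpha$ (default 0). Counts
are stored by neighbour count $d = 0..26$; formulas weight by dependence
size $j = d + 1$, i.e. the voxel itself is counted, which keeps the
$1/j^2$ small-dependence weights finite. The 14 features reuse the
run-length template (small/large dependence emphasis, gray-level and
dependence non-uniformity, variances, entropy, and the low/high gray-level
combinations).

## Modeling protocol and its numerical choices

Per split: an unstratified random 80/20 partition (redrawn, bounded, if
either side is single-class - "randomly separated" is taken literally while
keeping the AUC computable; stratified splitting is available behind
`modelingConfig(stratified = TRUE)`). Min-max normalization to [0, 1] is
fitted on the *training rows only* and applied unclipped to the test rows;
whole-cohort bounds would leak test information into the model. The inverse
penalty C is tuned by `cvRounds` x `cvFolds` inner cross-validation
maximizing mean validation AUC, with minority oversampling applied *inside
each inner-training fold only* (oversampling before folding would duplicate
rows across fold boundaries and inflate inner AUCs); ties resolve to the
strongest penalty. The final model is an L1-penalized logistic fit (glmnet,
`alpha = 1`, no internal standardization since features are pre-normalized)
on the oversampled training set; coefficients below 1e-8 count as exactly
zero, which is the embedded selection rule. The default grid spans 13
log-spaced points over 1e-3..1e3 on the inverse-penalty scale, from full
shrinkage to near-unpenalized.

The Spearman redundancy filter (|rho| > 0.8, greedy first-in-canonical-order
wins) is applied once to the full dosiomic tables before splitting, matching
the protocol narrative in which a fixed reduced feature set feeds all 1000
models; this is mildly leakage-prone (the filter sees all patients'
features, though never labels) and is documented as such.

All randomness flows from one master seed: per-split child seeds are drawn
first, and every split replays deterministically from its own seed
(`refitSplit`), which is how the leakage/reproducibility audit works.
Because partitions depend only on the seed, the patient count and the
labels, the four groups are modeled on identical partitions and the default
group comparison is a *paired* Z-test on per-split AUC differences; the
unpaired two-sample form is available. Repeated holdout splits of one cohort
overlap in patients, so the naive standard error $s_d/\sqrt{n}$ treats
correlated replicates as independent and is severely anti-conservative: on
null cohorts (labels independent of dose) it flags group differences at
p < 0.01 in roughly half of repeated simulations. The default therefore uses
the Nadeau-Bengio variance correction for resampled estimates,
$z = \bar{d}\,/\,\big(s_d\sqrt{1/n + n_{\text{test}}/n_{\text{train}}}\big)$,
which restores approximate calibration at the cost of power; the
uncorrected statistic is one flag away (`correction = "none"`). Degenerate
cases: all-zero differences give p = 1; zero-variance nonzero differences
give p = 0 with a warning. Even corrected, these p-values compare models *on
this cohort* and are comparative diagnostics rather than exact inference.

Odds ratios are reported per unit of the *raw* feature,
$\mathrm{OR} = \exp(\beta_{\text{norm}}/(\max - \min))$ with that split's
training bounds, summarized by median and 10th/90th percentiles across
splits. Splits where a feature was not selected contribute OR entries of 0
by default (`orIncludeZeros`), so a feature selected in just over half the
splits shows a 10th-percentile OR of 0; the exclusion convention is one flag
away.

## The synthetic cohort generator

No patient data ship with the package; `simulateCohort()` emulates the
statistical structure the analysis assumes, and its defaults are the study
conditions the tests run under:

* ~100 patients (desk preset 60; the recovery simulations below use 200),
  62% RP grade >= 1, grades drawn 38/57/5% for 0/1/2;
* prescriptions of 30-60 Gy at 1.8-3.0 Gy per fraction, with the fraction
  dose concentrated at 1.8 Gy;
* a two-lobed ellipsoidal lung mask with a mediastinal corridor cut out,
  24^3 voxels at 6 mm (the pipeline resamples to 1.5 mm);
* per-fraction dose fields composed of four Gaussian-profile beam templates
  (AP/PA/lateral) with per-patient field width and depth attenuation, all
  normalized to the sampled prescription at the target; with probability
  `beamHeterogeneity` (default 0.3) a fraction's beam weights are
  re-sampled - same target dose, different spatial distribution - which is
  exactly the mechanism that makes EQD2 differ from the physical sum;
* a multiplicative smooth noise field whose per-patient correlation length
  drives texture busyness (short correlation length = busy dose).

Outcomes are planted as
$\mathrm{RP} \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(b_0 +
 b_1 z(\mathrm{V40}) + b_2 z(\mathrm{busyness})))$, where the covariates are
*realized* native-grid feature values (stored as ground truth; honest
recovery tests need the realized value, not the nominal knob) and $b_0$ is
solved so the expected prevalence equals the specified positive fraction.
The V40 covariate is the realized V40 of the summed physical dose. The
texture covariate needs one subtlety: NGTDM busyness is gray-level
dependent, so computed on the raw dose it is strongly confounded with the
dose level (correlation about -0.8 with MLD in generated cohorts), and a
"texture-only" planted effect would be recoverable from the DVH. The stored
busyness covariate is therefore the realized busyness of the summed dose
rescaled to a common 20 Gy mean lung dose - a scale-free texture quantity
driven by the noise correlation length and essentially orthogonal to the
DVH features.
Default effects $b_1 = 1.2$, $b_2 = -1.2$ (busyness protective, mirroring
the direction typically reported) give cohort-level AUCs in the 0.65-0.8
range typical of published RP models; recovery presets plant a single
strong effect (|b| = 3).

What the generator does *not* emulate: real anatomy (no CT, no air/tissue
heterogeneity), planning-system dose calculation, inter-observer contouring
variability, or clinical covariates correlated with dose. Passing recovery
tests therefore demonstrates that the *pipeline* can detect and attribute
planted associations of realistic magnitude under realistic collinearity -
not that any specific feature predicts clinical RP.

A note on attribution under collinearity: adjacent DVH thresholds correlate
at 0.93-0.98 in generated cohorts (as they do in real ones), so which single
Vx the LASSO credits is sharply sample-dependent at n = 60. The V40-recovery
simulation therefore runs at n = 200 - the cohort size at which the planted
feature's selection frequency stabilizes above the 50% reporting criterion -
with 200 splits. Desk-scale modeling presets (200 splits, 2 x 5 inner CV,
7-point grid) keep full runs in minutes; the full-scale protocol
(1000 splits, 20 x 5 inner CV, 13-point grid) is `modelingConfig()`'s
default.

## Degenerate inputs and edge rules

* Masks are binarized at > 0.5 on read; empty masks are errors.
* Doses above the top discretization bin clamp to level 100 with a warning.
* Constant training features normalize to all zeros (warned) and can never
  be selected.
* Inner CV folds with single-class validation sides are skipped (warned);
  a split whose test side is single-class is redrawn, bounded.
* Vx uses the >= convention; the strict > variant is one flag away
  (`dvhSpec(strictInequality = TRUE)`) and differs only on exact dose ties.
* The gEUD is volume-averaged, $((1/N)\sum D_i^{1/n})^n$, which reduces to
  MLD at n = 1 and is voxel-count invariant; the unnormalized power-sum
  variant (which is neither) is available behind `geud(..., literal = TRUE)`
  for audit only.

## Known limitations

* DICOM RT-DOSE/RTSTRUCT are out of scope; supported formats are NIfTI,
  (axis-aligned) NRRD and the package's plain-text fixture grid.
* No wavelet/LoG-filtered feature classes, no 2D extraction, no shape
  features (shape is meaningless for a dose field in a fixed organ).
* One global alpha/beta; no spatial radiosensitivity maps, no BED or
  repopulation corrections, and hypofractionated regimens are untested
  territory for the EQD2 conversion as implemented.
* The repeated-holdout Z-test caveat above applies to all reported
  p-values.
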