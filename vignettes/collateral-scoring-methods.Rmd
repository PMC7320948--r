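---
title: "Whole-brain collateral scoring and outcome modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain collateral scoring and outcome modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collaterals)
```

## The scientific problem

In acute ischemic stroke, tissue distal to an occluded artery survives on
collateral routes: the circle of Willis, leptomeningeal (pial) anastomoses,
and retrograde flow through communicating arteries. Patients with good
collateral supply tend to have more salvageable penumbra, smaller final
infarcts and better discharge outcomes. This package implements a
whole-brain collateral vessel score computed from an ordinary
CT-angiography reading sheet, together with the statistical pipeline needed
to ask whether that score predicts radiological outcome (final infarct
volume, FIV) and clinical outcome (NIHSS and mRS at discharge) in an
unselected emergency-department cohort.

Because clinical cohort data of this kind cannot be redistributed, the
package ships a synthetic admission-cohort generator whose marginals and
planted effect structure emulate such a cohort. Every downstream stage —
scoring, univariate screening, regression, MANOVA, subgrouping, reporting —
is exercised against generated cohorts.

## The grading sheet and the score

Each patient's sheet grades every collateral-relevant vessel per side
(`vessel_slots()` enumerates the 34 slots):

* **Graded vessels** (VA, BAS, Pcom, ICA, Acom, and the ACA/MCA/PCA
  segments A1–A2, M1–M3, P1–P3): −4 occluded, −3 visible stenosis,
  −2 hypoplastic, −1 diameter variations, 0 not assessable, 1 normal.
* **Assessability-only vessels** (PICA, AICA, SCA, ophthalmic artery,
  middle meningeal artery): 1 assessable, 0 not assessable.
* **Pial collaterals**: a cortical count banded 0 (0–8 visible), 1 (9–11),
  2 (> 11), and a cerebellar count banded 0 (none/not assessable),
  1 (< 3), 2 (> 2).

Aggregation: left and right grades are added to give one value per vessel
(atherosclerotic change is assumed roughly symmetric); cerebral-artery
segments are then combined with proximal up-weighting, ACA = 2·A1 + A2,
MCA = 4·M1 + 2·M2 + M3, PCA = 4·P1 + 2·P2 + P3, because proximal disease is
the more devastating; the ICA enters as one side-summed factor. The
whole-brain score is the plain sum of all components:

```{r}
whole_brain_score(normal_vasculature())
```

An all-normal sheet scores 56; bilateral occlusion of every graded vessel
with nothing else assessable scores −168. Because every aggregation weight
is positive, improving any single grade can never lower the score — the
test suite asserts this by exhaustive single-slot perturbation.

Design choices worth stating, since the combination rule admits variants:

* **Unweighted final summation.** Vessel components, assessability points
  and pial scores are summed without further weighting — the most
  transparent choice, consistent with the additive construction of the
  components themselves.
* **Midline vessels.** BAS and Acom are anatomically unpaired and carry a
  single grade; it is not doubled.
* **"Not assessable" is neutral (0), not missing.** A slot that cannot be
  read contributes nothing. The alternative — treating 0 as missing and
  rescaling — would make scores incomparable across patients with
  different assessable sets; we keep the neutral convention and note that
  it places "not assessable" numerically above "diameter variations" (−1).
* **One ICA factor.** The ICA is graded once per side and side-summed,
  with no intra-ICA segment weighting.
* **Pial counts are whole-brain counts**, not per-hemisphere; a cerebellar
  count of 0 is indistinguishable from "not assessable" and maps to 0.
* Grade codes are validated strictly; unknown codes are errors, never
  coerced.

## The synthetic cohort generator

`generate_admissions()` draws a cohort along the chain *covariates → latent
atherosclerotic burden → vasculature grades → whole-brain score → latent
severity → treatment → outcomes*. The defaults describe an
emergency-department admission cohort: 686 admissions, 69 excluded for data
quality and 87 for an alternative diagnosis (analysis set 530); age
truncated-normal 65.7 ± 15.0 on [19, 90]; 60.9% male; atherosclerosis 33%,
smoking 39.1%, elevated admission glucose 5.3%, infection 2.5%, statin use
25% (a typical value for this age structure; no published anchor);
treatment IV thrombolysis 32.2%, IA thrombolysis (± bridging) 6%,
thrombectomy 2%, none 55.1% — the four printed proportions sum to 0.953
because treatment was evidently missing for some patients in the source
cohort, and the generator renormalises them to 1; 17.2% later reclassified
as TIA; territory mix 60% MCA, with the remainder spread over PCA, ACA,
vertebrobasilar and other territories (the source reports territory shares
only graphically, so these are a realistic choice, fixed once).

**Burden and vasculature.** The latent burden is
`plogis(−1.6 + 1.2·athero + 0.5·z(age) + 0.5·smoking + 0.6·glucose + N(0, 0.8))`
(mean ≈ 0.2: most suspected-stroke admissions have largely patent
vasculature). Given burden *b*, each graded slot is independently not
assessable with probability 0.02, degraded with probability 0.9·*b*
(degraded grades drawn from −1/−2/−3/−4 with weights 0.45/0.25/0.18/0.12),
otherwise normal; assessability slots are assessable with probability
0.97 − 0.4·*b*; pial counts are Poisson with means 12(1 − 0.55 *b*)
(cortical) and 3(1 − 0.55 *b*) (cerebellar). The resulting score
distribution has mean 17.6 and SD 27.2 (frozen as `score_center` /
`score_scale` from a 200,000-draw Monte Carlo of this chain); the expected
score is strictly decreasing in burden.

**Treatment.** Treatments are allocated at the exact configured counts by
ranking patients on an observable severity index (worse score, presence of
atherosclerosis or elevated glucose) plus independent jitter
(`treatment_confounding`, default SD 2.0, i.e. mild confounding): the most
severe patients receive thrombectomy, then IA, then IV thrombolysis. This
reproduces the clinically familiar pattern that treated patients have the
worse outcomes, while keeping the allocation a function of modelled
predictors plus independent noise — so regression recovery of the planted
treatment offsets remains unbiased.

**Outcomes.** With `z = (score − score_center)/score_scale` and a shared
severity noise term `h ~ N(0, 1)`:

* `log1p(FIV) = 2.24 − 0.55·z + 0.4·athero + 0.5·glucose + {0.4, 1.2, 1.0}
  for IV/IA/thrombectomy + 0.55·h + N(0, 0.48)`, floored at 0 and with
  FIV ≡ 0 for TIA records (a transient deficit leaves no persistent
  infarct).
* NIHSS and mRS arise by monotone binning of latent severities that share
  `h` (inducing inter-outcome correlations of roughly 0.4–0.7, the
  magnitude seen in discharge data, without fitting them exactly): NIHSS
  via a shifted `expm1` transform rounded into 0–42 (discharge median ≈ 1,
  admission median ≈ 6), mRS via fixed thresholds into 0–6 (discharge
  median 2).

**Calibration and its compromises.** The FIV intercept 2.24 was chosen (by
a one-off Monte Carlo at design time) so that about 66% of analysis records
fall below 15 ml given the 17.2% TIA point mass. A single log-normal
component cannot simultaneously match a ~2 ml median, 66% < 15 ml *and* a
13% mass above 100 ml; we prioritised the < 15 ml fraction (the generator's
stated fidelity check) and a floor-censoring rate low enough (≈ 0.3%) to
keep regression recovery unbiased. Consequences: the synthetic FIV median
is ≈ 8 ml rather than ≈ 2 ml, and only ~4% of records exceed 100 ml, so the
malignant-volume subgroup usually falls below the minimum-n guard and is
reported as "not analyzable" — which is in fact how such a subgroup behaves
in cohorts of this size. The source description also contains two
conflicting medians for FIV (2.76 vs 1.94 ml, evidently a mean/median
typo); we anchored on 1.94 ml when weighing this compromise.

What the generator does **not** emulate: the joint dependence structure of
real risk factors, missing-data patterns (real regression denominators are
visibly smaller than the analysis set; our records are complete unless the
user introduces missingness), measurement error in manual FIV reading, and
the extreme FIV tail. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated, not that real cohorts will show the
same effect sizes.

## The statistical pipeline

**Univariate screen.** Continuous predictors are tested with Pearson's *r*
(t test on n − 2 df); categorical predictors with a Pearson χ² test
(no continuity correction) summarised as Cramér's
V = √(χ²/(n·(min(r,c) − 1))). For a categorical predictor against a
continuous outcome, the outcome is binned into quartiles (collapsing tied
quantile breaks — relevant for the heavily discrete discharge NIHSS); the
binning is the conventional default since no canonical rule exists for
reporting V against a continuous outcome. Missing data are deleted
pairwise per association; p-values are reported raw, with no
multiple-testing adjustment — the report merely bolds p < α (default
0.05).

**Outcome models.** Each outcome is modelled by OLS on the 12-predictor
design (whole-brain score, pial-only score, atherosclerosis, glucose,
statin, smoking, infection, age, male sex, and three treatment dummies
against no intervention), with listwise deletion within each model.
Discharge mRS and NIHSS are ordinal but entered as continuous — a
deliberate fidelity-over-purity reproduction of common clinical practice,
noted as a limitation; ordinal models are out of scope. FIV enters as
log1p(FIV) by default (`fiv_transform = "raw"` is available) because the
raw scale is dominated by its extreme tail. Standardized β rescales each
coefficient by sd(x)/sd(y), binary dummies included — the convention of the
major commercial statistics packages. Overall F, R² and adjusted
R² = 1 − (1 − R²)(n − 1)/(n − p − 1) accompany each table.

**MANOVA.** The three outcomes are re-analysed jointly with Pillai's trace
(the usual default, robust to mild covariance heterogeneity; other
statistics are not implemented), per-predictor via type-III tests and
overall via the comparison against the intercept-only model. With a single
outcome column the Pillai F reduces exactly to the OLS overall F, which the
tests assert to 1e-6; a duplicated outcome column makes the residual
covariance singular and is rejected.

**Subgroups.** `subgroup_spec()` filters by territory, FIV band and NIHSS
threshold. Each spec carries a minimum-n guard (default 30, i.e. about 2.5
cases per predictor; at least predictors + 2 is enforced): below it the
subgroup is not fitted but reported as "not analyzable (n too small)",
mirroring how malignant-profile subgroups behave in practice. The default
set is: all patients, MCA territory only, medium-volume strokes
(15–100 ml), and the malignant profile (FIV > 100 ml).

**Determinism.** All randomness flows from the single seed passed to
`generate_admissions()` / `run_config()`; same (config, seed) gives
byte-identical cohort CSVs and report files. Provenance (seed, MD5 config
hash, package version) is embedded in every report and cohort sidecar.

## Numerical and edge-case conventions

* Grade validation is strict; incomplete sheets error with the missing
  slot names, duplicated slots are rejected.
* `pearson_r` errors on fewer than 3 complete pairs or zero variance;
  `cramers_v` errors on 1×k tables and all-zero margins (the screen drops
  empty rows/columns arising from quartile binning before testing).
* `fit_ols` errors on rank deficiency, naming the collinear columns, and
  on n ≤ p + 1 after listwise deletion.
* Report JSON carries full double precision; the markdown rendering rounds
  to 3 decimals and prints p < 0.001 as such.

## Problem sizes used by the test suite

The suite runs the statistic oracles on 1,000 random small problems each;
null calibration of the screen on 1,000 zero-effect cohorts of n = 530
(12 screen cells) with adjusted-R² calibration on 500 of them; and planted
parameter recovery on 200 default-config cohorts at the 530-patient
analysis scale. These sizes give Monte-Carlo standard errors comfortably
below the tolerances being asserted while keeping a full run in the
low minutes on a single CPU.

## Known limitations

* The whole-brain score's combination rule (unweighted summation) is one
  defensible choice among several; regional or lesion-side-relative
  weighting is explicitly future work and not implemented.
* Cramér's V between a binary predictor and a continuous outcome depends
  on the binning rule; quartile binning is configurable but not
  canonical.
* Ordinal outcomes in OLS and MANOVA inherit the usual caveats about
  treating ranked scales as interval data.
* The generator plants effects directly on the score; it cannot be used to
  study misspecification where collateral status affects outcome only
  through unmodelled channels.
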