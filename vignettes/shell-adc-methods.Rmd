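---
title: "Peritumoral shell ADC analysis: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral shell ADC analysis: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelladc)
```

## The measurement model

`shelladc` quantifies the diffusion microenvironment around a breast tumor
as a function of distance from the tumor surface. The inputs are a 3D ADC
map (units 10⁻³ mm²/s throughout — every function stores and reports in
this unit to avoid silent drift) and a co-registered binary tumor
segmentation; optionally an exclusion mask marking skin, pectoral muscle,
large vessels or macroscopic fat. The pipeline is:

1. **Isotropic resampling** to 1 mm voxels (tri-linear for the volume,
   nearest-neighbor with re-binarization for masks). Clinical DWI is
   acquired with ~3 mm slices; a 2 mm shell cannot be resolved on such a
   grid, so resampling precedes all geometry.
2. **One-voxel erosion** of the tumor with a 6-connected (face-adjacent)
   structuring element. At 1 mm isotropic spacing this removes exactly
   1 mm at faces; a 26-connected element would remove up to √3 mm at
   corners, which is why the cross-shaped element is used. The eroded
   mask defines the *intratumoral measurement VOI* only — its purpose is
   to keep boundary partial-volume signal out of both the tumor mean and
   the innermost shell.
3. **Distance field**: for every voxel, the Euclidean distance (physical
   mm) to the nearest tumor voxel, computed with a separable exact
   distance transform (Felzenszwalb–Huttenlocher, generalized to
   anisotropic spacing) in C++. Distances are measured from the
   **original, un-eroded** tumor boundary: the erosion serves signal
   hygiene, whereas shell distances are anatomical quantities. (The
   alternative reading — growing shells from the eroded boundary — would
   shift every shell inward by 1 mm; we consider the original boundary
   the anatomically meaningful reference and apply it consistently.)
4. **Shells**: half-open distance bands (0,2], (2,5], (5,10] mm. Half-open
   intervals make the conventional "0–2 / 2–5 / 5–10 mm" specification
   tile without overlap, so every voxel is assigned at most once. Shell
   voxels must lie outside the tumor, inside the grid, and outside the
   exclusion mask. Each shell carries two QC flags: `empty` (zero voxels,
   e.g. fully excluded) and `clipped` (tissue within the band's outer
   distance falls outside the image).
5. **Contralateral reference**: the tumor VOI reflected across the
   mid-plane of the left–right axis — a VOI of identical size at the same
   craniocaudal level in the other breast. Volumes are reoriented to a
   canonical RAS axis order on load precisely so that this mirror is well
   defined. The mirror is a fallback-free involution; if the reflected
   VOI would overlap the tumor (midline lesions), the function refuses
   and asks for a manually supplied reference mask instead.
6. **Metrics**: compartment means (voxel-wise average over the 3D
   compartment), rADC values (compartment mean / reference mean) and
   intratumoral-to-peritumoral ratios, all computed **per patient**. The
   cohort summary of a ratio is the median of patient-level ratios, never
   a ratio of cohort medians. Tumor volume is reported for the un-eroded
   mask (voxel count × voxel volume): erosion is a measurement device,
   volume an anatomical quantity.

Missing data policy: an empty or fully-missing compartment yields `NA`
(with a warning), never 0; downstream statistics drop patients pairwise.
This lets cohort-scale runs survive degenerate cases (e.g. a tumor so
small that erosion empties it — the eroded-VOI computation then falls
back to the un-eroded mask and flags `erosion_fallback`).

## Statistical layer

All headline analyses are nonparametric, reflecting the skewed,
median/IQR-summarized nature of ADC metrics: Mann–Whitney U for two
groups (exact enumeration when both groups have n ≤ 8 without ties,
normal approximation with continuity correction otherwise),
Kruskal–Wallis with tie correction and Bonferroni-adjusted pairwise post
hoc tests gated on the overall p < 0.05, and mid-rank Spearman
correlation. A parametric branch (Welch t, one-way ANOVA) is available
behind an opt-in flag. No global correction across metrics is applied;
Bonferroni adjustment only acts within a post hoc family. Degenerate
inputs are defined rather than undefined: fully tied two-group data give
p = 1, all-constant k-group data give H = 0, p = 1.

Interobserver agreement uses ICC(2,1): two-way random effects, absolute
agreement, single measurement, from the mean-squares decomposition. This
is the strictest of the common ICC variants (it penalizes systematic
rater offsets), an appropriate default when the agreement design mixes
different observers and re-reads over time.

## Decision layer

ROC curves are empirical: every unique marker value is a candidate
cutoff, plus the two degenerate endpoints. Rule direction is explicit —
`low_predicts_positive` markers (tumor ADC, rADC, ratios: restriction
means aggression) classify score ≤ cutoff as positive — and scores are
oriented internally so that higher always means more likely positive,
avoiding silent AUC < 0.5 ambiguity. The AUC is the Mann–Whitney
estimator with tie weight ½; its variance, confidence interval and the
paired two-curve test use the DeLong placement-value decomposition (the
test suite cross-checks both against `pROC`).

Operating points report **achieved** empirical rates, never interpolated
ones: the fixed-specificity rule selects the threshold with the smallest
achieved specificity ≥ the target; Youden ties break toward higher
specificity, then the lower cutoff. Confusion-matrix reconstruction from
published (sensitivity, specificity, n₊, n₋) uses half-up rounding of
tp and tn, which is the unique convention that reproduces every mutually
consistent PPV/NPV cell of the reference operating-point table with
27/41 group sizes. (That table's accuracy column is internally
inconsistent with its own sensitivity/specificity for every non-Youden
row; the reconstruction targets only the mutually consistent cells.)

Internal validation:

- **Cross-validation** is stratified by outcome (5 folds × 200 repeats by
  default). `cv_mean_auc`/`cv_sd` summarize *fold-level* test AUCs: with
  n = 68 a test fold holds ~13 patients, and the reported SD (~0.13) is
  the spread of fold-level AUCs — repeat-level averaging would shrink it
  threefold and misrepresent the fold-to-fold instability that motivates
  repeated CV in the first place.
- **Bootstrap optimism correction** resamples subjects with replacement
  (unstratified, standard practice), computes each resample rule's AUC on
  the resample and on the original data, and subtracts the mean gap from
  the apparent AUC. For a fixed single marker nothing is refit, so
  optimism is ~0 by construction; for the logistic-model mode the model
  is refit per resample. Per-resample Youden cutoffs give the cutoff
  stability median/IQR.
- Both procedures draw from deterministic seed streams
  (`seed + 1000·repeat`, `seed + 2000000 + iteration`), so a
  `validation_result` is bit-reproducible from its base seed.

Frozen-threshold evaluation (`apply_frozen_threshold`) applies a
previously derived cutoff to a new cohort with no re-optimization, the
correct protocol for temporally independent validation.

## Synthetic data: what it emulates, and what it does not

**Phantoms** place an ellipsoidal tumor in the right half of a bilateral
1 mm grid. Compartment ADC levels default to the study-population
medians: tumor 0.88, shells 1.52 / 1.42 / 1.57 (note the non-monotonic
radial gradient: the 2–5 mm band is the most restricted peritumoral
zone), background and contralateral reference 1.55. Compartment
membership is decided by the Euclidean distance field of the voxelized
tumor mask — the same canonical distance definition the pipeline uses —
so a zero-noise phantom is recovered exactly; analytic test oracles use
digital spheres, where the closed form |x − c| − R is available
independently. Additive Gaussian noise defaults to SD 0.1 × 10⁻³ mm²/s,
a realistic magnitude for 1.5 T breast ADC maps; optional "adipose"
blocks with aberrant ADC can be dropped into the outer band to exercise
the exclusion-mask path. (Adipose tissue in vivo has *low* ADC; the
blocks default to 0.40 accordingly.)

**Cohorts** draw the five compartment ADCs from a Gaussian copula
(pairwise correlation 0.5 on the log scale — a modeling choice, since
within-patient cross-compartment dispersion is not published) with
per-pN-group log-normal margins parameterized by median and IQR, matching
how such data are reported. rADC and ratio metrics are derived by
per-patient division, so the metric identities hold exactly. Ki-67,
grade, and LVI load (−0.5) on the idiosyncratic part of the
intratumoral-ADC latent, which reproduces the observed sign pattern:
tumor ADC and all ratios correlate negatively with grade/Ki-67 while
shell ADCs stay near zero. Tumor volume is log-normal
(median 3999 mm³, IQR 1123–9618) with its group separation set to an
AUC of 0.655.

Two calibration modes exist because they answer different questions.
*Anchor mode* honors the published group medians/IQRs of each
compartment; but ratios derived under the copula have smaller dispersion
than real patient ratios (the shared factor cancels in the quotient), so
anchor-mode ratio AUCs run high (~0.87). *Target-AUC mode* replaces a
named marker with a draw whose group separation is exactly
Δ = √2·Φ⁻¹(AUC) on the latent scale, mapped through pooled log-normal
margins (a monotone transform, so the AUC is preserved). AUC-level
claims are therefore always exercised in target-AUC mode; distributional
claims (medians, cutoffs) in anchor mode.

What passing tests on these generators do **not** show: robustness to
real segmentation variability, partial-volume mixing at the tumor
boundary, spatially correlated (non-white) noise, B₀/EPI distortion, or
fibroglandular-vs-adipose tissue heterogeneity. The phantom is a
geometric instrument, not an MRI simulator.

## Numerical choices and known limitations

- **Distance definition.** Distances are voxel-center to voxel-center.
  On a digital sphere this overestimates the distance to the continuous
  surface by roughly half a voxel and, for *thin* bands, the jagged
  digital surface pushes borderline voxels out of the band: the (0,2]
  shell of an R = 10 mm digital sphere holds ~16% fewer voxels than the
  continuous closed form 4π/3·((R+2)³ − R³), while the 2–5 and 5–10 mm
  bands agree within ~3%. This is an intrinsic discretization property
  (an independent distance-transform implementation reproduces the voxel
  counts exactly), relevant when comparing thin-shell volumes — not
  shell means — against analytic expectations.
- **Resampling grid.** The resampled grid keeps the original origin and
  the largest voxel-center extent that stays inside the original volume,
  so no extrapolation ever occurs; edge voxels clamp.
- **Erosion at image borders** treats outside-of-grid as background, so
  a tumor touching the border erodes there too.
- **Zero-variance DeLong cases** (perfect separation, or all scores
  tied) are reported with a collapsed CI and a `degenerate` flag rather
  than NaNs; fully tied scores give AUC 0.5, p = 1.
- **Separation in logistic fits** is detected (non-convergence, runaway
  coefficients, or saturated fitted probabilities) and raised as an
  error — no pseudo-estimates are emitted.
- **Problem sizes.** The test suite and the acceptance script exercise
  cohorts of n = 68 (27 positives) — the study-population geometry — with
  500 cohort replicates for calibration checks, 1000 replicates for the
  DeLong size check, and full-size validation runs (5 × 200 CV, 2000
  bootstrap iterations); phantom grids are 96 × 64 × 48 at 1 mm and
  oracle grids ≤ 40³, where the brute-force O(N·M) references remain
  tractable.
- The package analyzes given ADC maps; it does not fit multi-b-value
  models, perform registration, or segment anything. Shell thickness
  below the native slice thickness is only meaningful after the
  resampling step, and the 0–2 mm shell in particular inherits whatever
  boundary uncertainty the input segmentation carries.
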