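# shelladc

Multilayered peritumoral shell ADC analysis for breast MRI.

## The problem

In invasive breast cancer, the tissue immediately surrounding the tumor —
the peritumoral microenvironment — carries prognostic information that
intratumoral measurements alone miss. On diffusion-weighted MRI, the
apparent diffusion coefficient (ADC, ×10⁻³ mm²/s) quantifies water
mobility: low values indicate dense, cellular tissue. `shelladc`
implements a distance-resolved analysis of that microenvironment: starting
from a 3D ADC map and a binary tumor segmentation, it

1. resamples everything to 1 mm isotropic voxels,
2. erodes the tumor by one voxel (6-connected) to keep tumor signal out of
   the peritumoral measurements,
3. grows concentric peritumoral shells at 0–2, 2–5 and 5–10 mm from the
   (un-eroded) tumor surface using an exact Euclidean distance transform,
4. mirrors the tumor VOI across the midsagittal plane to obtain a
   contralateral reference VOI of equal size at the same anatomical level,
5. computes, per patient, the mean ADC of each compartment, normalized
   ADC values (rADC = compartment ADC / reference ADC), and
   intratumoral-to-peritumoral ratios
   (ratioₖ = tumor ADC / shell-k ADC, computed per subject),

and then provides the decision-analytic layer used to evaluate such
markers against histopathological outcomes (axillary lymph node status,
lymphovascular invasion, molecular subtype, grade, Ki-67): Mann–Whitney /
Kruskal–Wallis comparisons with Bonferroni post hoc, Spearman
correlations, ICC(2,1) reproducibility, empirical ROC curves with DeLong
inference (AUC vs 0.5 and paired curve comparison), Youden and
fixed-sensitivity/specificity operating points, confusion-matrix
reconstruction from published rates, logistic models with clinically
scaled odds ratios (per +0.1 unit; tumor volume per doubling), repeated
stratified 5-fold cross-validation, and bootstrap optimism correction
with cutoff-stability analysis.

Because clinical ADC datasets are rarely shareable, the package also ships
first-class synthetic generators: ADC phantoms with analytic ground-truth
geometry, and patient cohorts with log-normal marker distributions that
are either anchored to published group medians/IQRs or calibrated to a
target AUC via the binormal separation Δ = √2·Φ⁻¹(AUC).

## Core quantities

For tumor mask T on volume grid Ω, the distance field is
d(x) = min_{t∈T} ‖x − t‖ (mm, physical spacing). Shell k is
{x : innerₖ < d(x) ≤ outerₖ} \ (T ∪ exclusion), with half-open bands
(0,2], (2,5], (5,10]. Per patient:

- rADC_c = ADC̄_c / ADC̄_reference for each compartment c,
- ratioₖ = ADC̄_tumor / ADC̄_shellₖ (values < 1 mean the tumor is more
  diffusion-restricted than its surroundings),
- AUC and its DeLong variance from placement values; Youden cutoff
  maximizes J = sensitivity + specificity − 1;
- optimism-corrected AUC = apparent AUC − mean(AUC on bootstrap resample
  − AUC of the resample rule on the original data).

## Worked example

```r
library(shelladc)

# noiseless phantom: compartments set to the cohort medians
ph <- generate_phantom(phantom_spec(noise_sd = 0))
m  <- extract_patient_metrics(ph$volume, ph$truth,
                              reference_voi = ph$reference_voi)
round(unlist(m[c("adc_tumor", "adc_shell1", "adc_shell2",
                 "adc_shell3", "adc_reference")]), 3)
#>     adc_tumor    adc_shell1    adc_shell2    adc_shell3 adc_reference
#>          0.88          1.52          1.42          1.57          1.55
round(unlist(m[c("radc_tumor", "ratio_shell1", "ratio_shell2",
                 "ratio_shell3")]), 3)
#>   radc_tumor ratio_shell1 ratio_shell2 ratio_shell3
#>        0.568        0.579        0.620        0.561
```

The pipeline recovers the configured compartment values exactly; the
ratios are the per-patient divisions (0.88/1.52 = 0.579, and so on).

```r
# synthetic 68-patient cohort, ratio_shell1 calibrated to AUC 0.725
co <- generate_cohort(cohort_sim_spec(
  target_auc = list(ratio_shell1 = 0.725), seed = 1))
cv <- roc_curve(co$ratio_shell1, co$pN_status, "low_predicts_positive")
delong_auc_inference(cv)
#> AUC 0.698 (95% CI 0.567-0.830), p = 0.0031 vs AUC = 0.5
youden_cutoff(cv)
#> operating_point [youden]: cutoff 0.4602, sens 0.593, spec 0.780,
#>   ppv 0.640, npv 0.744, acc 0.706
validate_internal(scores = co$ratio_shell1, labels = co$pN_status,
                  rule_direction = "low_predicts_positive", seed = 17)
#> validation_result: apparent AUC 0.698, CV 0.698 (sd 0.138),
#>   corrected 0.697 (optimism +0.0013), boot 95% CI [0.565, 0.826]
```

A single cohort draw of n = 68 lands within sampling noise of its 0.725
calibration target; a fixed marker is not refit, so cross-validation
tracks the apparent AUC and the bootstrap optimism is near zero.

A command-line front end over the same functions lives at
`inst/cli/shelladc.R` (subcommands `shells`, `metrics`, `simulate`,
`roc`).

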