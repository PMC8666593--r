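# adiposemri

Adipose characteristics of the seated buttocks from sagittal T1-weighted
MRI, for pressure-injury (PrI) research in full-time wheelchair users.

Sustained seated loading changes the soft tissue under the ischial
tuberosity (IT), and those changes may signal biomechanical risk for
pressure injuries. This package quantifies two such signatures on a single
sagittal slice through the IT peak, given manual segmentations of the
pelvis/ischium, gluteus maximus and subcutaneous fat (SubQF, skin
included):

* **SubQF effect size** — how much darker the subcutaneous adipose directly
  under the ischium is than the adipose surrounding it;
* **IMAT effect size** — how much fat has infiltrated the gluteus maximus,
  read from the contrast between muscle and a posterior subcutaneous
  reference.

Both use the same standardized statistic, a Cohen's-d-style effect size with
the pooled standard deviation:

    d(A, B) = (mean(I_A) - mean(I_B)) / s_p
    s_p     = sqrt(((n_A-1) s_A^2 + (n_B-1) s_B^2) / (n_A + n_B - 2))

with SubQF = d(surrounding, under) — positive means darker under the
ischium — and IMAT = d(reference adipose, gluteus) — near-zero or negative
means heavy or complete infiltration. Around these sit the full pipeline:

* phantom-based correction of the vertical surface-coil intensity gradient
  (power-law normalization curve `a*(h + y0)^b + c`, subtracted per height);
* IT-peak location and the 10-mm / 5-mm region rules anchoring the SubQF
  comparison to the ischium footprint;
* biomechanical-risk measures: bulk tissue thickness under the IT (50-mm
  window) and the sagittal radius of curvature of the inferior bone contour
  (Taubin circle fit);
* a midpoint-threshold IMAT comparator for cross-checking the effect-size
  ranking;
* the cohort statistics stage: one-way ANOVA group comparisons, Pearson
  correlations with subject covariates, complete-infiltration exclusion
  (IMAT effect size < 0), and participant-characteristics summaries;
* a synthetic-data module (phantoms, single subjects, whole cohorts with
  known ground truth) so everything is testable without clinical scans.

Results are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` visualisations. Images travel as NIfTI, landmarks
and curves as JSON, tables as CSV, configs as YAML. A thin CLI dispatcher
(`inst/cli/adiposemri`) exposes the verbs `simulate-cohort`, `fit-coil`,
`correct`, `extract-rois`, `metrics`, `stats` and `run-all`.

## Worked example

```r
library(adiposemri)

# Phantom calibration scan and fitted normalization curve
ph <- generate_phantom_scan(c(3000, -0.5, 10), noise_sd = 20, seed = 2)
curve <- fit_normalization_curve(ph)
curve
#> <normalization_curve> I(h) = 3319 * (h + 11.37)^-0.5288 + 1811  (rms 1.946)

# One synthetic subject generated with a known SubQF contrast of 0.58,
# analysed end to end (correction, ROI extraction, all metrics)
sub <- generate_subject_slice(subject_params(subqf_contrast = 0.58, seed = 7))
row <- run_subject(sub$slice, sub$seg, curve = curve, subject_id = "S01")
row[, c("subqf_effect_size", "imat_effect_size",
        "bulk_thickness_mm", "sagittal_radius_mm")]
#>   subqf_effect_size imat_effect_size bulk_thickness_mm sagittal_radius_mm
#> 1             0.574            0.287            15.294             81.226
```

The measured SubQF effect size (0.574) recovers the generative 0.58 up to
scanner noise; thickness and radius sit within pixel quantization of their
generative 14.8 mm and 83.7 mm.

```r
# A full synthetic cohort (21 subjects without PrI history, 22 with),
# through the whole pipeline including the statistics battery
res <- run_cohort(pipeline_config(synthetic = list(n_no_pri = 21, n_pri = 22),
                                  seed = 101))
res
#> <cohort_results> 43 subjects analysed, 0 failed, 11 fully infiltrated excluded
#>   34 statistics rows; correction on

dplyr::filter(res$stats, subset == "all", analysis == "anova",
              group == "pri_history")
#>               metric estimate conf.low conf.high p.value
#> 1  subqf_effect_size   -0.410   -0.742    -0.078   0.017
#> 2   imat_effect_size    0.387    0.013     0.762   0.043
#> 3  bulk_thickness_mm    4.910    1.208     8.611   0.011
#> 4 sagittal_radius_mm   36.751   21.596    51.906   0.000
```

`estimate` is mean(no-history group) − mean(history group): this simulated
cohort recovers its generated structure — the PrI-history group has darker
under-ischium adipose (difference −0.41, near the generative −0.37),
thinner tissue and a more peaked ischium.

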