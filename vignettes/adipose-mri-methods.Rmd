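---
title: "Methods: adipose characteristics of the seated buttocks from sagittal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adipose characteristics of the seated buttocks from sagittal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposemri)
```

## The problem

Full-time wheelchair users carry sustained, high-magnitude load on the
soft tissue under the ischial tuberosities (ITs), and are at elevated risk of
pressure injuries (PrIs). Two adipose depots are of interest on a seated
sagittal T1-weighted MRI slice through the IT peak:

* **Subcutaneous fat (SubQF)** — the layer between skin and deep fascia.
  In some individuals the adipose directly under the ischium appears darker
  than the adipose surrounding it, a possible signature of load-induced
  tissue change.
* **Intramuscular adipose tissue (IMAT)** — fat infiltrated within the
  gluteus maximus. On T1 images fat is bright and muscle dark, so
  infiltration raises the apparent muscle intensity.

Both are quantified with the same standardized statistic, a Cohen's-d-style
effect size between two pixel populations:

$$d(A, B) \;=\; \frac{\bar I_A - \bar I_B}{s_p},
\qquad
s_p = \sqrt{\frac{(n_A-1)s_A^2 + (n_B-1)s_B^2}{n_A+n_B-2}}.$$

* **SubQF effect size** $= d(\text{adipose surrounding the ischium},
  \text{adipose under the ischium})$: positive values mean darker adipose
  under the ischium.
* **IMAT effect size** $= d(\text{reference adipose posterior to the
  ischium}, \text{gluteus maximus})$: large positive values mean lean
  muscle; values near zero or negative mean heavy infiltration, and a
  negative value (muscle brighter than fat) is read as *complete*
  infiltration.

The pooled SD uses the $(n-1)$-weighted two-sample form. "Pooled standard
deviation" is otherwise ambiguous; this is the standard Cohen's-d reading.
The statistic is exactly invariant to affine intensity maps
$x \mapsto sx + o$ ($s>0$), which the test suite checks to $10^{-12}$ —
this invariance is what makes the downstream numbers indifferent to the
brightness-preserving constant the gradient correction adds back.

Two biomechanical-risk measures accompany the adipose statistics: **bulk
tissue thickness** (mean soft-tissue depth under the IT over a 50-mm
anterior–posterior window; thinner = higher risk) and the **sagittal radius
of curvature** of the inferior bone contour over a 50-mm window at the IT
peak (smaller radius = more peaked = higher risk).

## Coil-gradient correction

Seated scans are acquired with a planar surface coil under the cushion, so
intensity falls off with height above the coil plane. The correction is
phantom-based and one-dimensional: a homogeneous fluid-filled ball is
scanned with the same sequence, the mean in-mask intensity at each height
$h$ (mm above the inferior image edge) is fit by least squares to

$$I(h) = a\,(h + y_0)^{b} + c,$$

and subject slices are corrected by subtracting the fitted curve at each
pixel's height. The package then adds back the curve's image-height mean so
intensities keep their familiar scale; effect sizes are invariant to this
constant, so it changes nothing downstream.

Numerical choices:

* The per-height means are weighted by their in-mask pixel counts — heights
  that cut the edge of the spherical phantom average few pixels and are
  noisier.
* The fit is Levenberg–Marquardt from a small multi-start grid over the
  origin and exponent, seeded by weighted linear least squares for $(a, c)$.
* A flat profile (no resolvable gradient) short-circuits to an
  amplitude-zero curve rather than a degenerate nonlinear fit.
* With all four parameters free, $(a, b, y_0, c)$ are only *jointly*
  identified at moderate noise: the fitted curve is accurate (and the
  correction unaffected) but individual coefficients trade off along a
  ridge. When the coil-plane offset is known — it is scanner geometry —
  pass it as `origin_mm`; the three remaining parameters are then recovered
  to a few percent at realistic phantom noise.
* The curve is fit to per-height means rather than all voxels; with the
  per-height weights the two are equivalent for a homogeneous phantom, and
  the profile is what the curve model describes.

Whether the SubQF comparison strictly requires correction is moot here —
correction is motivated by the IMAT comparison, which spans different
heights — so this pipeline corrects before *all* metrics. For the SubQF
statistic the residual effect is small because both regions sit at similar
heights.

## Region geometry

All regions are anchored to the **IT peak**: the most inferior pixel of the
ischium mask; ties on the lowest row resolve to the anterior–posterior
centroid of the tied set, rounded toward anterior. Pixel indices are
1-based (R convention) and mm positions are $(\text{index}-1)\times
\text{spacing}$, with row 1 superior and column 1 anterior.

* **10-mm band**: all SubQF pixels at or inferior to the level 10 mm
  superior to the peak. This bounds the analysis and keeps visceral adipose
  out.
* **Under the ischium**: band pixels whose AP position lies within the
  ischium's AP footprint (computed within the band's height range) extended
  by 5 mm on each side — the margin attaches to the bone's extent, not to a
  point, because the region is "anterior and posterior *of the ischium*".
  The interval is closed on both sides on pixel centres.
* **Surrounding**: the rest of the band. Under and surrounding partition
  the band exactly — a property the tests enforce against a brute-force
  pixel-enumeration oracle. No outer AP limit is imposed on the
  surrounding region.
* **IMAT reference adipose**: SubQF pixels strictly posterior to the peak
  and inferior to the gluteus maximus' inferior boundary at each AP
  position (columns with no gluteus use the mask's overall inferior
  extent). The gluteus region is the whole gluteus mask.

Bulk thickness is measured **vertically** (bone inferior boundary to outer
skin boundary, averaged over the 50-mm window). The original oblique-plane
construction lives in prior work that is not restated in the source; the
vertical depth in the seated posture is the defensible desk-scale reading
and is flagged as an open choice, not a settled fact. The radius of
curvature uses a Taubin algebraic circle fit on the per-column inferior
bone contour within 50 mm of arc length — deterministic, needing no
initialization, exact on noiseless circles; collinear contours return an
infinite radius with a warning instead of a number.

The midpoint-threshold comparator (threshold halfway between the reference
adipose mean and the gluteus intensity mode below it; IMAT fraction = share
of gluteus pixels above threshold) is implemented as a documented stand-in
for the classical cutoff approach, used only to sanity-check the
effect-size ranking; it is flagged, not silently returned, for very lean or
fully infiltrated muscles where the two populations are not separable.

## The synthetic-data generator

No clinical scans ship with the package, so the generator is first-class,
tested code. It emulates:

* a homogeneous phantom: a circular region at constant base intensity,
  plus the additive power-law falloff and Gaussian noise;
* single subjects: an ischium shell whose inferior contour is a circular
  arc of radius `it_radius_mm` with a unique inferior peak; a gluteus block
  posterior/superior to it; a SubQF layer (skin = its outermost two pixel
  rows) running under bone and gluteus down to a flat cushion plane placed
  so the mean tissue depth over the 50-mm window equals
  `tissue_thickness_mm` up to pixel quantization;
* cohorts: per-subject parameters drawn from two group distributions.

Key generative choices:

* **Noise is additive Gaussian**, not Rician: at the intensity scale of
  these scans (thousands of units against noise SDs of tens) the Gaussian
  approximation is excellent and keeps generation analytic.
* **The gradient is additive**, `a*(h + y0)^b` with `y0 > 0`, matching the
  subtraction-based correction and avoiding the singularity at the coil
  plane. Texture, then gradient, then scanner noise.
* **The SubQF contrast is calibrated exactly**: after compartment textures
  are drawn, the under-ischium region (as the extractor defines it) is
  shifted by the exact amount that makes the realized effect size equal
  `subqf_contrast`. Noiseless round-trips therefore recover the parameter
  to floating-point precision, not merely in expectation.
* **Infiltrated gluteus pixels are drawn brighter than subcutaneous fat**
  (mean multiplier 1.15). With equal means, full infiltration would sit at
  an effect size of 0; the brighter draw reproduces the clinically observed
  signature in which a fully infiltrated muscle is *brighter* than the
  reference adipose and the effect size goes negative (about −0.7 at
  fraction 1 under defaults, inside the reported clinical range).
* **Cohort defaults are the study conditions**: group sizes 21/22; SubQF
  contrast means 0.21/0.58 (SDs 0.56/0.45); thickness 17.1/12.5 mm;
  radius 93.9/73.6 mm; years of wheelchair use 10.7/19.6 (positively
  correlated, ρ = 0.45, with the infiltration fraction); spasm rates
  0.56/0.70 with a negative logistic coupling to infiltration (spasms ↔
  leaner muscle); BMI 24.5/23.3; compressible hip breadth 1.7/1.1 in;
  missingness 5/43 (spasms) and 4/43 (hip breadth). The infiltration
  fractions (means 0.30/0.39, SDs 0.30/0.26) are set through the measured
  fraction→effect mapping (≈ 1.19 − 1.99·fraction at default intensities)
  so rendered IMAT effect sizes centre near 0.59/0.41 with SD ≈ 0.55 and
  roughly a sixth of subjects cross into complete infiltration.
* Absolute tissue intensity distributions are not published for these
  scans; compartment means (fat 2000, muscle 1320, bone 400) and texture
  SDs (500/380/150) were chosen once to match the printed region-mean and
  effect-size scales and are not revisited.

What the generator does **not** emulate — and hence what green tests do not
show about clinical data: partial-volume mixing at compartment boundaries,
Rician noise floors in air, anatomical variation of mask shapes (the masks
are exact by construction, whereas manual segmentation carries
inter-observer error), motion or susceptibility artefacts, and any 3-D
structure (a single sagittal slice is generated, matching the analysis).

## Cohort statistics

Group comparisons are one-way ANOVAs; with two groups this is algebraically
the pooled two-sided t test ($F = t^2$), an identity the suite asserts on
random inputs. The CI of the group difference is the pooled-variance t
interval, consistent with the ANOVA's equal-variance assumption. Pearson
correlations relate the effect sizes to BMI, years of wheelchair use,
compressible hip breadth and the biomechanical measures, with
pairwise-complete deletion so each analysis reports its own n. No
multiple-testing adjustment is applied — the analysis stage is exploratory
by design and p values are reported raw.

Complete fat infiltration (IMAT effect size < 0) is excluded in a secondary
pass; the boundary value 0 is kept, and the removal count is reported. One
reported interval in the source tables cannot bracket its own point
estimate (a difference printed as −0.370 with interval [−0.684, −0.555]);
the package implements the standard pooled-t interval and makes no attempt
to imitate the inconsistent printout.

## Problem sizes and seeds

Defaults generate 176×256 px slices at 1 mm spacing (a 256-mm field of view
at typical in-plane resolution) and 192×192 phantoms. Monte-Carlo
properties use: 20 seeds for noisy phantom-parameter recovery, 50 subjects
for SubQF recovery under default noise, and 500 parameter-level replicate
cohorts for CI coverage and type-I error (the statistical properties attach
to the inference procedure, so replicate cohorts are drawn at the parameter
level rather than rendered as images). Every stochastic step flows from a
single integer seed; regeneration is bit-identical.

## A worked example

```{r example, eval = FALSE}
res <- run_cohort(pipeline_config(synthetic = list(n_no_pri = 21, n_pri = 22),
                                  seed = 101))
res
dplyr::filter(res$stats, subset == "all", analysis == "anova")
```

## Known limitations

* The oblique-plane thickness and the exact construction of the posterior
  reference-adipose boundary are pictorial in the source; the vertical
  depth and the posterior/inferior predicate implemented here are each one
  faithful reading, documented above.
* The midpoint comparator is a stand-in estimator, used for ranking checks
  only.
* With all four curve parameters free, coefficient recovery (not curve
  accuracy) degrades at low SNR; supply `origin_mm` when the coil geometry
  is known.
* Real masks are hand-drawn; all mask-dependent error sources are absent
  from the synthetic ground truth.
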