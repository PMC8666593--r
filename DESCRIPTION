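Package: adiposemri
Title: Adipose Characteristics of the Seated Buttocks from Sagittal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies subcutaneous and intramuscular adipose characteristics
    of the seated buttocks from a single sagittal T1-weighted MRI slice, for
    pressure-injury research in full-time wheelchair users. Implements
    phantom-based correction of the vertical surface-coil intensity gradient
    (power-law normalization curve), extraction of ischium-anchored regions of
    interest around the ischial-tuberosity peak, standardized effect-size
    statistics for subcutaneous fat darkening under the ischium and for fat
    infiltration of the gluteus maximus (pooled-SD Cohen's-d convention), a
    midpoint-threshold comparator, biomechanical-risk measures (bulk tissue
    thickness and sagittal radius of curvature via Taubin circle fit), and the
    cohort statistics stage (one-way ANOVA group comparisons, Pearson
    correlations, full-infiltration exclusion, participant summaries). A
    synthetic-data module generates phantom scans, single subjects and whole
    cohorts with known ground truth so the entire pipeline is testable without
    access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
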