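#' Pipeline configuration
#'
#' A single object driving the whole phantom-fit -> correction -> ROI ->
#' metrics -> cohort-statistics pipeline. Exactly one of `synthetic` (cohort
#' generator settings) or `inputs` (paths to real scans/masks) must be given.
#'
#' @param synthetic `NULL`, or a list with `n_no_pri`, `n_pri` and optionally
#'   `group_params` (defaults to [default_group_params()]).
#' @param inputs `NULL`, or a list of per-subject input paths: each element a
#'   list with `id`, `scan`, `labels`, and optionally `landmark`; plus
#'   top-level `phantom`, `phantom_mask` and `covariates` (CSV path).
#' @param margin_mm,band_mm,window_mm Region parameters (defaults 5, 10, 50).
#' @param correction Apply the coil-gradient correction (default `TRUE`).
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory for CSV/JSON artefacts, or `NULL` to skip
#'   writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(n_no_pri = 21, n_pri = 22),
                            inputs = NULL,
                            margin_mm = 5, band_mm = 10, window_mm = 50,
                            correction = TRUE, seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) == is.null(inputs)) {
    abort("Exactly one of `synthetic` or `inputs` must be specified.")
  }
  if (margin_mm <= 0 || band_mm <= 0 || window_mm <= 0) {
    abort("Region margins must be strictly positive.")
  }
  structure(list(synthetic = synthetic, inputs = inputs,
                 margin_mm = margin_mm, band_mm = band_mm,
                 window_mm = window_mm, correction = isTRUE(correction),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] stage '%s': %s", subject_id, stage, conditionMessage(e)))
  })
}

#' Run the per-subject analysis
#'
#' Applies the gradient correction (when a curve is supplied), locates the IT
#' peak, extracts the SubQF and IMAT regions, and computes all adipose and
#' biomechanical metrics for one subject. Deterministic given its inputs;
#' any stage failure is re-raised tagged with the stage name and subject id.
#'
#' @param slice A [sagittal_slice()] (raw; corrected internally if `curve`
#'   is supplied).
#' @param seg A [segmentation_set()].
#' @param curve Optional `normalization_curve`; `NULL` skips correction.
#' @param subject_id Identifier used in outputs and error messages.
#' @param margin_mm,band_mm,window_mm Region parameters.
#' @return A one-row tibble: `subject_id`, the [compute_adipose_metrics()]
#'   columns, `midpoint_fraction`, `midpoint_flagged`, `bulk_thickness_mm`,
#'   `sagittal_radius_mm`.
#' @export
run_subject <- function(slice, seg, curve = NULL, subject_id = "subject",
                        margin_mm = 5, band_mm = 10, window_mm = 50) {
  if (!is_sagittal_slice(slice)) abort(sprintf("[%s] invalid slice input.", subject_id))
  if (!is_segmentation_set(seg)) abort(sprintf("[%s] invalid segmentation input.", subject_id))
  corrected <- if (!is.null(curve)) {
    with_stage("correction", subject_id, correct_slice(slice, curve))
  } else {
    slice
  }
  landmark <- with_stage("landmark", subject_id, find_it_peak(seg))
  subqf <- with_stage("subqf_regions", subject_id,
                      extract_subqf_regions(corrected, seg, landmark,
                                            margin_mm = margin_mm,
                                            band_mm = band_mm))
  imat <- with_stage("imat_regions", subject_id,
                     extract_imat_regions(corrected, seg, landmark))
  metrics <- with_stage("adipose_metrics", subject_id,
                        compute_adipose_metrics(subqf$under, subqf$surrounding,
                                                imat$ref_adipose, imat$gluteus))
  mp <- with_stage("midpoint", subject_id,
                   midpoint_imat_fraction(imat$ref_adipose, imat$gluteus))
  thick <- with_stage("thickness", subject_id,
                      bulk_tissue_thickness(seg, landmark, window_mm = window_mm))
  radius <- with_stage("curvature", subject_id, suppressWarnings(
    sagittal_radius_of_curvature(bone_inferior_contour(seg), landmark,
                                 window_mm = window_mm)))
  dplyr::bind_cols(
    tibble(subject_id = subject_id), metrics,
    tibble(midpoint_fraction = mp$fraction, midpoint_flagged = mp$flagged,
           bulk_thickness_mm = thick, sagittal_radius_mm = radius)
  )
}

#' Run the full statistics battery on a cohort table
#'
#' Group comparisons (one-way ANOVA) of the four metrics by pressure-injury
#' history, spasms comparisons of both effect sizes, and the Pearson
#' correlations of the effect sizes with covariates and biomechanical-risk
#' measures. Analyses whose preconditions fail on the given table (missing
#' columns, degenerate groups) are skipped rather than fatal.
#'
#' @param table Cohort data frame (metrics joined with covariates).
#' @param subset Label recorded in the output's `subset` column.
#' @return A tibble with one row per comparison or correlation.
#' @export
cohort_stat_battery <- function(table, subset = "all") {
  out <- list()
  add <- function(x) out[[length(out) + 1]] <<- x
  safe_glance <- function(expr) tryCatch(glance(expr), error = function(e) NULL)
  safe_cor <- function(expr) tryCatch(expr, error = function(e) NULL)

  for (m in c("subqf_effect_size", "imat_effect_size",
              "bulk_thickness_mm", "sagittal_radius_mm")) {
    g <- safe_glance(group_compare(table, m, "pri_history"))
    if (!is.null(g)) add(mutate(g, analysis = "anova", .before = 1))
  }
  for (m in c("imat_effect_size", "subqf_effect_size")) {
    g <- safe_glance(group_compare(table, m, "spasms"))
    if (!is.null(g)) add(mutate(g, analysis = "anova", .before = 1))
  }

  pairs <- list(
    c("subqf_effect_size", "bmi"), c("subqf_effect_size", "years_wheelchair"),
    c("subqf_effect_size", "hip_breadth_in"),
    c("imat_effect_size", "bmi"), c("imat_effect_size", "years_wheelchair"),
    c("imat_effect_size", "hip_breadth_in"),
    c("subqf_effect_size", "bulk_thickness_mm"),
    c("subqf_effect_size", "sagittal_radius_mm"),
    c("imat_effect_size", "bulk_thickness_mm"),
    c("imat_effect_size", "sagittal_radius_mm"),
    c("subqf_effect_size", "imat_effect_size")
  )
  for (p in pairs) {
    r <- safe_cor(correlate(table, p[1], p[2]))
    if (!is.null(r)) {
      add(dplyr::bind_cols(tibble(analysis = "pearson",
                                  metric = p[1], group = p[2]),
                           dplyr::select(r, -"x", -"y")))
    }
  }
  res <- bind_rows(out)
  if (nrow(res)) mutate(res, subset = subset, .before = 1) else res
}

#' Run the full cohort pipeline
#'
#' Synthetic mode: generates a phantom scan and a whole cohort, fits the
#' normalization curve, corrects and analyses every subject, joins the
#' covariates, and runs the statistics battery (group comparisons of all four
#' metrics by pressure-injury history, spasms comparisons, covariate and
#' biomechanical correlations), both on all subjects and after excluding
#' complete fat infiltration. Per-subject failures are collected, not fatal.
#'
#' @param config A [pipeline_config()] (or a list/YAML path coercible to one).
#' @return An object of class `cohort_results`: tibbles `metrics` (per
#'   subject), `table` (metrics joined with covariates), `stats`, `summary`,
#'   plus `curve`, `truth` (synthetic mode), `n_excluded` and `failures`.
#'   When `config$out_dir` is set, `metrics.csv`, `cohort_table.csv`,
#'   `stats.csv`, `summary.csv` and `curve.json` are written there.
#' @export
run_cohort <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gp <- syn$group_params %||% default_group_params()
    cohort <- generate_cohort(n_no_pri = syn$n_no_pri %||% 21,
                              n_pri = syn$n_pri %||% 22,
                              group_params = gp, seed = config$seed,
                              render = TRUE)
    phantom <- generate_phantom_scan(gradient = gp$shared$gradient,
                                     noise_sd = gp$shared$noise_sd / 4,
                                     spacing_mm = gp$shared$spacing_mm,
                                     seed = config$seed + 1L)
    subjects <- purrr::map(cohort$subjects, function(s) list(slice = s$slice, seg = s$seg))
    covariates <- dplyr::select(cohort$truth, "subject_id", "pri_history",
                                "ischial_pri", "spasms", "years_wheelchair",
                                "bmi", "hip_breadth_in")
    truth <- cohort$truth
  } else {
    loaded <- load_real_inputs(config$inputs)
    phantom <- loaded$phantom
    subjects <- loaded$subjects
    covariates <- loaded$covariates
    truth <- NULL
  }
  if (!length(subjects)) abort("Empty cohort: no subjects to analyse.")

  curve <- if (config$correction) fit_normalization_curve(phantom) else NULL

  failures <- list()
  metric_rows <- purrr::imap(subjects, function(s, id) {
    tryCatch(run_subject(s$slice, s$seg, curve = curve, subject_id = id,
                         margin_mm = config$margin_mm, band_mm = config$band_mm,
                         window_mm = config$window_mm),
             error = function(e) {
               failures[[id]] <<- conditionMessage(e)
               NULL
             })
  })
  metrics <- bind_rows(metric_rows)
  if (nrow(metrics) == 0) abort("Every subject failed; see the failure manifest.")

  table <- left_join(metrics, covariates, by = "subject_id")
  stats_all <- cohort_stat_battery(table, subset = "all")
  kept <- suppressMessages(exclude_full_infiltration(table))
  n_excluded <- attr(kept, "n_excluded")
  stats_excl <- if (nrow(kept) >= 4) {
    cohort_stat_battery(kept, subset = "excluding_full_infiltration")
  } else {
    NULL
  }
  stats <- bind_rows(stats_all, stats_excl)
  summary <- cohort_summary(dplyr::select(table, -dplyr::starts_with("adipose_"),
                                          -dplyr::starts_with("gluteus_")))

  res <- structure(list(metrics = metrics, table = table, stats = stats,
                        summary = summary, curve = curve, truth = truth,
                        n_excluded = n_excluded, failures = failures,
                        config = config),
                   class = "cohort_results")
  if (!is.null(config$out_dir)) write_cohort_results(res, config$out_dir)
  res
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("<cohort_results> %d subjects analysed, %d failed, %d fully infiltrated excluded\n",
              nrow(x$metrics), length(x$failures), x$n_excluded))
  cat(sprintf("  %d statistics rows; correction %s\n", nrow(x$stats),
              if (is.null(x$curve)) "off" else "on"))
  invisible(x)
}

# Read per-subject real inputs described in a pipeline_config 'inputs' list.
load_real_inputs <- function(inputs) {
  if (is.null(inputs$phantom)) abort("`inputs$phantom` (path) is required.")
  phantom_slice <- read_slice_nifti(inputs$phantom)
  mask <- if (!is.null(inputs$phantom_mask)) {
    read_mask_nifti(inputs$phantom_mask)
  } else {
    abort("`inputs$phantom_mask` (path) is required.")
  }
  covariates <- if (!is.null(inputs$covariates)) {
    readr::read_csv(inputs$covariates, show_col_types = FALSE)
  } else {
    tibble(subject_id = character(0))
  }
  subjects <- lapply(inputs$subjects, function(s) {
    list(slice = read_slice_nifti(s$scan), seg = read_labels_nifti(s$labels))
  })
  names(subjects) <- vapply(inputs$subjects, `[[`, character(1), "id")
  list(phantom = structure(list(slice = phantom_slice, mask = mask),
                           class = "phantom_scan"),
       subjects = subjects, covariates = covariates)
}
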