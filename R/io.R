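#' Read and write slices, masks and landmarks
#'
#' Images travel as NIfTI (2-D slices stored as single-slice volumes, pixel
#' spacing in the header), label masks as one integer-coded NIfTI volume
#' (1 = pelvis/ischium, 2 = gluteus maximus, 3 = SubQF incl. skin), landmarks
#' and normalization curves as JSON, tables as CSV and pipeline configs as
#' YAML.
#'
#' @param slice A [sagittal_slice()].
#' @param path File path.
#' @param slice_thickness_mm Through-plane voxel size recorded in the header
#'   (default 3 mm contiguous slices).
#' @return `write_*` functions return `path` invisibly; `read_*` functions
#'   return the reconstructed object.
#' @name slice_io
NULL

#' @rdname slice_io
#' @export
write_slice_nifti <- function(slice, path, slice_thickness_mm = 3) {
  stopifnot(is_sagittal_slice(slice))
  arr <- array(slice$intensity, dim = c(dim(slice$intensity), 1L))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(slice$spacing_mm, slice$spacing_mm, slice_thickness_mm)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname slice_io
#' @export
read_slice_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
  sagittal_slice(matrix(as.numeric(arr), nrow(arr), ncol(arr)),
                 spacing_mm = RNifti::pixdim(nii)[1])
}

label_codes <- c(ischium = 1L, gluteus = 2L, subqf = 3L)

#' @rdname slice_io
#' @param seg A [segmentation_set()].
#' @export
write_labels_nifti <- function(seg, path, slice_thickness_mm = 3) {
  stopifnot(is_segmentation_set(seg))
  lab <- matrix(0L, nrow(seg$ischium), ncol(seg$ischium))
  for (nm in names(label_codes)) lab[seg[[nm]]] <- label_codes[[nm]]
  nii <- RNifti::asNifti(array(lab, dim = c(dim(lab), 1L)))
  RNifti::pixdim(nii) <- c(seg$spacing_mm, seg$spacing_mm, slice_thickness_mm)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname slice_io
#' @export
read_labels_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
  lab <- matrix(as.integer(round(arr)), nrow(arr), ncol(arr))
  segmentation_set(ischium = lab == label_codes[["ischium"]],
                   gluteus = lab == label_codes[["gluteus"]],
                   subqf = lab == label_codes[["subqf"]],
                   spacing_mm = RNifti::pixdim(nii)[1])
}

#' @rdname slice_io
#' @export
read_mask_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
  matrix(arr > 0, nrow(arr), ncol(arr))
}

#' @rdname slice_io
#' @param landmark An `it_landmark`.
#' @export
write_landmark_json <- function(landmark, path) {
  jsonlite::write_json(unclass(landmark), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slice_io
#' @export
read_landmark_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(row = as.integer(x$row), col = as.integer(x$col),
                 height_mm = x$height_mm, ap_mm = x$ap_mm,
                 spacing_mm = x$spacing_mm %||% 1),
            class = "it_landmark")
}

#' @rdname slice_io
#' @param curve A `normalization_curve`.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "normalization_curve"))
  jsonlite::write_json(
    list(amplitude = curve$amplitude, exponent = curve$exponent,
         origin_mm = curve$origin_mm, offset = curve$offset,
         fit_residual_rms = curve$fit_residual_rms,
         spacing_mm = curve$spacing_mm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slice_io
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_normalization_curve(x$amplitude, x$exponent, x$origin_mm, x$offset,
                          x$fit_residual_rms %||% NA_real_,
                          x$spacing_mm %||% 1,
                          tibble(height_mm = numeric(0),
                                 mean_intensity = numeric(0),
                                 n_px = integer(0)))
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

#' Write one synthetic subject to disk
#'
#' Emits the scan and label masks as NIfTI, the landmark and ground truth
#' (generative parameters) as JSON.
#'
#' @param subject A `synthetic_subject` from [generate_subject_slice()].
#' @param dir Output directory (created if needed).
#' @param id Subject identifier used as the file stem.
#' @return The directory, invisibly.
#' @export
write_subject <- function(subject, dir, id = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_slice_nifti(subject$slice, file.path(dir, paste0(id, "_scan.nii")))
  write_labels_nifti(subject$seg, file.path(dir, paste0(id, "_labels.nii")))
  write_landmark_json(subject$truth$landmark,
                      file.path(dir, paste0(id, "_landmark.json")))
  p <- subject$truth$params
  jsonlite::write_json(
    list(subqf_contrast = p$subqf_contrast, imat_fraction = p$imat_fraction,
         tissue_thickness_mm = p$tissue_thickness_mm,
         it_radius_mm = p$it_radius_mm, noise_sd = p$noise_sd,
         gradient = as.list(p$gradient), seed = p$seed,
         covariates = p$covariates),
    file.path(dir, paste0(id, "_truth.json")), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Persist the cohort_results tables for audit.
write_cohort_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(res$table, file.path(dir, "cohort_table.csv"))
  readr::write_csv(res$stats, file.path(dir, "stats.csv"))
  readr::write_csv(res$summary, file.path(dir, "summary.csv"))
  if (!is.null(res$truth)) readr::write_csv(res$truth, file.path(dir, "truth.csv"))
  if (!is.null(res$curve)) write_curve_json(res$curve, file.path(dir, "curve.json"))
  invisible(dir)
}
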