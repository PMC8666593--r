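#' Locate the ischial-tuberosity peak
#'
#' The landmark is the most inferior pixel of the ischium mask (the "peak" of
#' the ischial tuberosity in the seated sagittal plane). If several pixels tie
#' on the most inferior row, the landmark column is the anterior-posterior
#' centroid of the tied set, rounded toward anterior (floor).
#'
#' @param seg A [segmentation_set()], or a logical ischium mask.
#' @param spacing_mm Pixel spacing; taken from `seg` when it is a
#'   segmentation set.
#' @return An object of class `it_landmark`: `row`, `col` (1-based pixel
#'   indices), `height_mm` (superior-inferior position, mm from the superior
#'   edge) and `ap_mm` (anterior-posterior position, mm from the anterior
#'   edge).
#' @examples
#' m <- matrix(FALSE, 10, 10); m[7:8, 4:6] <- TRUE
#' find_it_peak(m, spacing_mm = 1)
#' @export
find_it_peak <- function(seg, spacing_mm = NULL) {
  if (is_segmentation_set(seg)) {
    mask <- seg$ischium
    spacing_mm <- spacing_mm %||% seg$spacing_mm
  } else {
    mask <- seg
    spacing_mm <- spacing_mm %||% 1
  }
  if (!is.matrix(mask) || !is.logical(mask)) abort("Ischium mask must be a logical matrix.")
  if (!any(mask)) abort("Ischium mask is empty; cannot locate the IT peak.")
  idx <- which(mask, arr.ind = TRUE)
  r_max <- max(idx[, 1])
  tied_cols <- idx[idx[, 1] == r_max, 2]
  col <- as.integer(floor(mean(tied_cols)))
  structure(list(row = as.integer(r_max), col = col,
                 height_mm = row_position_mm(r_max, spacing_mm),
                 ap_mm = col_position_mm(col, spacing_mm),
                 spacing_mm = spacing_mm),
            class = "it_landmark")
}

#' @export
print.it_landmark <- function(x, ...) {
  cat(sprintf("<it_landmark> px (%d, %d) | %.1f mm inferior, %.1f mm posterior\n",
              x$row, x$col, x$height_mm, x$ap_mm))
  invisible(x)
}

#' Extract the under- and surrounding-ischium SubQF regions
#'
#' Implements the 10-mm / 5-mm rule anchoring the subcutaneous analysis to
#' the ischial tuberosity:
#'
#' 1. The band is every SubQF pixel at or inferior to the level 10 mm
#'    superior to the IT peak (`band_mm`).
#' 2. The ischium footprint is the anterior-posterior extent of the ischium
#'    mask within that same height range.
#' 3. "Under the ischium" is the subset of the band whose AP position lies in
#'    the closed interval footprint +/- `margin_mm` (default 5 mm);
#'    "surrounding" is the rest of the band. The two partition the band.
#'
#' Pixel membership uses pixel-centre mm positions ((index-1) * spacing).
#'
#' @param slice The (typically gradient-corrected) [sagittal_slice()]
#'   providing intensities.
#' @param seg A [segmentation_set()].
#' @param landmark An [find_it_peak()] landmark; located from `seg` if `NULL`.
#' @param margin_mm AP margin beyond the ischium footprint (default 5 mm).
#' @param band_mm Height of the band above the IT peak (default 10 mm).
#' @return A list with tibbles `under` and `surrounding` (columns `region`,
#'   `row`, `col`, `row_mm`, `col_mm`, `intensity`) plus the `footprint`
#'   AP extent (mm) and the band threshold used.
#' @export
extract_subqf_regions <- function(slice, seg, landmark = NULL,
                                  margin_mm = 5, band_mm = 10) {
  stopifnot(is_sagittal_slice(slice), is_segmentation_set(seg))
  check_slice_seg(slice, seg)
  if (margin_mm <= 0 || band_mm <= 0) abort("Margins must be strictly positive.")
  landmark <- landmark %||% find_it_peak(seg)
  if (!any(seg$subqf)) abort("Region 'subqf' is empty.")
  sp <- seg$spacing_mm

  threshold_mm <- landmark$height_mm - band_mm
  subqf_px <- mask_pixels(seg$subqf, sp, slice)
  band <- dplyr::filter(subqf_px, .data$row_mm >= threshold_mm)
  if (nrow(band) == 0) abort("Region 'band' is empty: no SubQF within the band.")

  isch_px <- mask_pixels(seg$ischium, sp)
  isch_band <- dplyr::filter(isch_px, .data$row_mm >= threshold_mm)
  if (nrow(isch_band) == 0) {
    abort("Region 'footprint' is empty: no ischium within the band height range.")
  }
  fmin <- min(isch_band$col_mm); fmax <- max(isch_band$col_mm)

  in_under <- band$col_mm >= fmin - margin_mm & band$col_mm <= fmax + margin_mm
  under <- mutate(band[in_under, ], region = "adipose_under")
  surrounding <- mutate(band[!in_under, ], region = "adipose_surrounding")
  if (nrow(under) == 0) abort("Region 'under' is empty.")
  if (nrow(surrounding) == 0) abort("Region 'surrounding' is empty.")
  list(under = under, surrounding = surrounding,
       footprint = c(min_mm = fmin, max_mm = fmax),
       band_threshold_mm = threshold_mm)
}

#' Extract the IMAT analysis regions
#'
#' The intramuscular-fat comparison uses the whole gluteus maximus mask and a
#' subcutaneous reference constrained to the region posterior to the ischial
#' tuberosity and inferior to the gluteus maximus: SubQF pixels strictly
#' posterior to the landmark's AP position and inferior to the gluteus mask's
#' inferior boundary at each AP position (columns with no gluteus use the
#' mask's overall inferior extent).
#'
#' @inheritParams extract_subqf_regions
#' @return A list with tibbles `ref_adipose` and `gluteus` (same columns as
#'   [extract_subqf_regions()]).
#' @export
extract_imat_regions <- function(slice, seg, landmark = NULL) {
  stopifnot(is_sagittal_slice(slice), is_segmentation_set(seg))
  check_slice_seg(slice, seg)
  if (!any(seg$gluteus)) abort("Region 'gluteus' is empty.")
  landmark <- landmark %||% find_it_peak(seg)
  sp <- seg$spacing_mm

  gluteus <- mutate(mask_pixels(seg$gluteus, sp, slice), region = "gluteus")

  # Inferior boundary of the gluteus per column (0 where absent).
  g_bottom <- apply(seg$gluteus, 2, function(colv) {
    w <- which(colv); if (length(w)) max(w) else 0L
  })
  g_global <- max(g_bottom)
  subqf_px <- mask_pixels(seg$subqf, sp, slice)
  bound <- ifelse(g_bottom[subqf_px$col] > 0L, g_bottom[subqf_px$col], g_global)
  keep <- subqf_px$col_mm > landmark$ap_mm & subqf_px$row > bound
  ref <- mutate(subqf_px[keep, ], region = "adipose_posterior")
  if (nrow(ref) == 0) abort("Region 'ref_adipose' is empty.")
  list(ref_adipose = ref, gluteus = gluteus)
}
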