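#' Sagittal MRI slice container
#'
#' A single 2-D intensity image with isotropic in-plane pixel spacing and a
#' fixed axis convention: row 1 is the most superior row and row indices grow
#' in the inferior direction (towards the cushion and the receiver coil);
#' column 1 is the most anterior column and column indices grow posteriorly.
#' Millimetre positions are `(index - 1) * spacing_mm`, so the superior edge
#' and the anterior edge sit at 0 mm.
#'
#' @param intensity Numeric matrix of pixel intensities (arbitrary scanner
#'   units; T1-weighted convention, fat bright and muscle darker).
#' @param spacing_mm In-plane pixel spacing in mm per pixel (single positive
#'   number; pixels are assumed square).
#' @return An object of class `sagittal_slice`: a list with elements
#'   `intensity` and `spacing_mm`.
#' @examples
#' s <- sagittal_slice(matrix(100, 8, 8), spacing_mm = 1)
#' dim(s$intensity)
#' @export
sagittal_slice <- function(intensity, spacing_mm = 1) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix.")
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 ||
      !is.finite(spacing_mm) || spacing_mm <= 0) {
    abort("`spacing_mm` must be a single positive number.")
  }
  structure(list(intensity = intensity, spacing_mm = as.numeric(spacing_mm)),
            class = "sagittal_slice")
}

#' @export
print.sagittal_slice <- function(x, ...) {
  cat(sprintf("<sagittal_slice> %d x %d px @ %.3g mm/px (%.3g x %.3g mm)\n",
              nrow(x$intensity), ncol(x$intensity), x$spacing_mm,
              nrow(x$intensity) * x$spacing_mm,
              ncol(x$intensity) * x$spacing_mm))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

is_sagittal_slice <- function(x) inherits(x, "sagittal_slice")

#' Per-row height above the coil plane
#'
#' The surface coil lies in the axial plane under the cushion, i.e. below the
#' inferior image edge. The coil-distance coordinate used by the gradient
#' model and the normalization curve is therefore measured upwards from the
#' inferior image edge: the bottom pixel row has height 0.
#'
#' @param slice A [sagittal_slice()].
#' @return Numeric vector, one height in mm per image row (row 1 first).
#' @export
coil_height_mm <- function(slice) {
  stopifnot(is_sagittal_slice(slice))
  nr <- nrow(slice$intensity)
  (nr - seq_len(nr)) * slice$spacing_mm
}

row_position_mm <- function(row, spacing_mm) (row - 1) * spacing_mm
col_position_mm <- function(col, spacing_mm) (col - 1) * spacing_mm

#' Flatten a slice to a pixel table
#'
#' @param slice A [sagittal_slice()].
#' @return A tibble with one row per pixel: `row`, `col` (1-based indices),
#'   `row_mm`, `col_mm` (mm from the superior/anterior edges) and `intensity`.
#' @export
slice_pixels <- function(slice) {
  stopifnot(is_sagittal_slice(slice))
  nr <- nrow(slice$intensity)
  nc <- ncol(slice$intensity)
  tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    row_mm = row_position_mm(rep(seq_len(nr), times = nc), slice$spacing_mm),
    col_mm = col_position_mm(rep(seq_len(nc), each = nr), slice$spacing_mm),
    intensity = as.vector(slice$intensity)
  )
}

#' Segmentation set for one sagittal slice
#'
#' Bundles the three manually segmented label masks used by the analysis:
#' pelvis/ischium, gluteus maximus and subcutaneous fat (SubQF). Skin, when
#' visible, is part of the SubQF mask because the scan resolution does not
#' support segmenting it separately. Masks must be logical matrices with the
#' same dimensions, co-registered to the slice they describe, and pairwise
#' disjoint.
#'
#' @param ischium,gluteus,subqf Logical matrices (TRUE = pixel in compartment).
#' @param spacing_mm Pixel spacing in mm (must match the slice).
#' @return An object of class `segmentation_set`.
#' @export
segmentation_set <- function(ischium, gluteus, subqf, spacing_mm = 1) {
  masks <- list(ischium = ischium, gluteus = gluteus, subqf = subqf)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.matrix(m) || !is.logical(m)) {
      abort(sprintf("`%s` must be a logical matrix.", nm))
    }
  }
  d <- dim(ischium)
  if (!identical(d, dim(gluteus)) || !identical(d, dim(subqf))) {
    abort("All masks must share the same dimensions.")
  }
  if (any(ischium & gluteus) || any(ischium & subqf) || any(gluteus & subqf)) {
    abort("Masks must be pairwise disjoint.")
  }
  structure(list(ischium = ischium, gluteus = gluteus, subqf = subqf,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf(
    "<segmentation_set> %d x %d px @ %.3g mm/px | ischium %d px, gluteus %d px, subqf %d px\n",
    nrow(x$ischium), ncol(x$ischium), x$spacing_mm,
    sum(x$ischium), sum(x$gluteus), sum(x$subqf)))
  invisible(x)
}

is_segmentation_set <- function(x) inherits(x, "segmentation_set")

check_slice_seg <- function(slice, seg) {
  if (!identical(dim(slice$intensity), dim(seg$ischium))) {
    abort("Slice and segmentation dimensions differ.")
  }
  if (abs(slice$spacing_mm - seg$spacing_mm) > 1e-9) {
    abort("Slice and segmentation pixel spacings differ.")
  }
  invisible(TRUE)
}

# Pixel table for one logical mask, with intensities from `slice` if given.
mask_pixels <- function(mask, spacing_mm, slice = NULL, region = NA_character_) {
  idx <- which(mask, arr.ind = TRUE)
  out <- tibble(
    region = region,
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    row_mm = row_position_mm(as.numeric(idx[, 1]), spacing_mm),
    col_mm = col_position_mm(as.numeric(idx[, 2]), spacing_mm)
  )
  if (!is.null(slice)) out$intensity <- slice$intensity[idx]
  out
}
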