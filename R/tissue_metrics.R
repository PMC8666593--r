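region_values <- function(x, arg = "region") {
  if (is.data.frame(x)) {
    if (!"intensity" %in% names(x)) {
      abort(sprintf("`%s` has no `intensity` column.", arg))
    }
    x <- x$intensity
  }
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric or a region table.", arg))
  x[is.finite(x)]
}

pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
}

#' Standardized intensity effect size between two pixel regions
#'
#' The core statistic of the analysis: a Cohen's-d-style standardized mean
#' difference, `(mean(a) - mean(b)) / s_p`, with the pooled standard
#' deviation in its (n-1)-weighted two-sample form
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' It is antisymmetric in its arguments and invariant to affine intensity
#' maps `x -> s*x + o` with `s > 0`, which is what makes it robust to the
#' global add-back constant of the gradient correction.
#'
#' @param a,b Numeric intensity vectors, or region tibbles with an
#'   `intensity` column (as returned by the extraction functions). Each needs
#'   at least 2 values.
#' @return A single unitless number.
#' @examples
#' effect_size(c(3, 4, 5), c(1, 2, 3))  # 2
#' @export
effect_size <- function(a, b) {
  a <- region_values(a, "a"); b <- region_values(b, "b")
  if (length(a) < 2 || length(b) < 2) {
    abort("Each region needs at least 2 intensities for an effect size.")
  }
  sp <- pooled_sd(a, b)
  if (!is.finite(sp) || sp == 0) {
    abort("Pooled SD is zero; the effect size is undefined.")
  }
  (mean(a) - mean(b)) / sp
}

#' Per-subject adipose metrics
#'
#' Combines the four extracted regions into the two effect-size statistics:
#' the SubQF effect size `effect_size(surrounding, under)` (positive = darker
#' adipose under the ischium) and the IMAT effect size
#' `effect_size(ref_adipose, gluteus)` (large positive = lean muscle; values
#' near zero or negative = substantial fat infiltration).
#'
#' @param under,surrounding SubQF region tables from
#'   [extract_subqf_regions()].
#' @param ref_adipose,gluteus IMAT region tables from
#'   [extract_imat_regions()].
#' @return A one-row tibble: `subqf_effect_size`, `imat_effect_size`, and
#'   mean/sd/n for each of the four regions
#'   (`adipose_surrounding_*`, `adipose_under_*`, `adipose_posterior_*`,
#'   `gluteus_*`).
#' @export
compute_adipose_metrics <- function(under, surrounding, ref_adipose, gluteus) {
  vals <- list(adipose_surrounding = region_values(surrounding, "surrounding"),
               adipose_under = region_values(under, "under"),
               adipose_posterior = region_values(ref_adipose, "ref_adipose"),
               gluteus = region_values(gluteus, "gluteus"))
  out <- tibble(
    subqf_effect_size = effect_size(vals$adipose_surrounding, vals$adipose_under),
    imat_effect_size = effect_size(vals$adipose_posterior, vals$gluteus)
  )
  for (nm in names(vals)) {
    out[[paste0(nm, "_mean")]] <- mean(vals[[nm]])
    out[[paste0(nm, "_sd")]] <- sd(vals[[nm]])
    out[[paste0(nm, "_n")]] <- length(vals[[nm]])
  }
  out
}

#' Midpoint-threshold IMAT fraction (comparator)
#'
#' Threshold-based comparator used to validate the effect-size approach: the
#' cutoff is the midpoint between the reference-adipose mean and the mode of
#' the gluteus intensities below that mean (the muscle mode); the IMAT
#' fraction is the proportion of gluteus pixels at or above the cutoff.
#' For very lean or fully infiltrated muscles the two intensity populations
#' are not separable and the result is flagged rather than returned silently.
#'
#' @param ref_adipose,gluteus Region tables or numeric vectors.
#' @return A one-row tibble: `fraction`, `threshold`, `adipose_mean`,
#'   `gluteus_mode`, `flagged` (TRUE when the muscle mode is not resolvable
#'   below the adipose mean).
#' @export
midpoint_imat_fraction <- function(ref_adipose, gluteus) {
  fat <- region_values(ref_adipose, "ref_adipose")
  glut <- region_values(gluteus, "gluteus")
  if (length(fat) < 2 || length(glut) < 10) {
    abort("Regions too small for the midpoint method.")
  }
  a_mean <- mean(fat)
  below <- glut[glut < a_mean]
  flagged <- FALSE
  if (length(below) < max(10, 0.05 * length(glut))) {
    # Essentially no gluteus signal below the adipose mean: full infiltration.
    flagged <- TRUE
    mode_est <- if (length(below) > 1) mean(below) else a_mean
  } else {
    d <- density(below, n = 512)
    mode_est <- d$x[which.max(d$y)]
  }
  if (!(a_mean > mode_est)) flagged <- TRUE
  thr <- (a_mean + mode_est) / 2
  tibble(fraction = mean(glut >= thr), threshold = thr,
         adipose_mean = a_mean, gluteus_mode = mode_est, flagged = flagged)
}

#' Bulk tissue thickness under the ischial tuberosity
#'
#' Biomechanical-risk measure: the mean vertical soft-tissue depth, over an
#' AP window (default 50 mm) centred at the IT peak, from the inferior
#' boundary of the ischium to the outer skin boundary. Soft tissue is the
#' union of the SubQF and gluteus masks; columns without bone or without soft
#' tissue below the bone are skipped.
#'
#' @param seg A [segmentation_set()].
#' @param landmark An `it_landmark`; located from `seg` if `NULL`.
#' @param window_mm AP window length (default 50 mm).
#' @return Thickness in mm (single number).
#' @export
bulk_tissue_thickness <- function(seg, landmark = NULL, window_mm = 50) {
  stopifnot(is_segmentation_set(seg))
  if (window_mm <= 0) abort("`window_mm` must be strictly positive.")
  landmark <- landmark %||% find_it_peak(seg)
  sp <- seg$spacing_mm
  soft <- seg$subqf | seg$gluteus
  cols <- seq_len(ncol(soft))
  col_mm <- col_position_mm(cols, sp)
  in_win <- abs(col_mm - landmark$ap_mm) <= window_mm / 2
  depths <- c()
  for (c in cols[in_win]) {
    bone_rows <- which(seg$ischium[, c])
    if (!length(bone_rows)) next
    b <- max(bone_rows)
    soft_rows <- which(soft[, c])
    soft_below <- soft_rows[soft_rows > b]
    if (!length(soft_below)) next
    depths <- c(depths, (max(soft_below) - b) * sp)
  }
  if (!length(depths)) {
    abort("No tissue columns in the thickness window.")
  }
  mean(depths)
}

#' Inferior bone contour as an ordered point set
#'
#' Per-column most-inferior ischium pixel, in mm coordinates, ordered
#' anterior to posterior; input for [sagittal_radius_of_curvature()].
#'
#' @param seg A [segmentation_set()].
#' @return Tibble with `x` (AP position, mm) and `y` (superior-inferior
#'   position, mm).
#' @export
bone_inferior_contour <- function(seg) {
  stopifnot(is_segmentation_set(seg))
  if (!any(seg$ischium)) abort("Ischium mask is empty.")
  sp <- seg$spacing_mm
  cols <- which(colSums(seg$ischium) > 0)
  tibble(
    x = col_position_mm(cols, sp),
    y = vapply(cols, function(c) row_position_mm(max(which(seg$ischium[, c])), sp),
               numeric(1))
  )
}

# Taubin algebraic circle fit (deterministic, exact on noiseless circles).
# Returns c(cx, cy, r); r = Inf flags a degenerate (collinear) point set.
circle_fit_taubin <- function(x, y) {
  n <- length(x)
  xm <- mean(x); ym <- mean(y)
  u <- x - xm; v <- y - ym
  z <- u^2 + v^2
  zm <- mean(z)
  if (zm < .Machine$double.eps) return(c(xm, ym, Inf))
  Z <- cbind((z - zm) / (2 * sqrt(zm)), u, v)
  sv <- svd(Z)
  A <- sv$v[, 3]
  A1 <- A[1] / (2 * sqrt(zm))
  # Circle equation A1*(x^2+y^2) + A2*x + A3*y + A4 = 0 in centred coords.
  A4 <- -zm * A1
  if (abs(A1) < 1e-10 * sqrt(A[2]^2 + A[3]^2) / max(sqrt(zm), 1)) {
    return(c(xm, ym, Inf))
  }
  cx <- -A[2] / (2 * A1)
  cy <- -A[3] / (2 * A1)
  r <- sqrt(cx^2 + cy^2 - A4 / A1)
  c(cx + xm, cy + ym, r)
}

#' Sagittal radius of curvature at the IT peak
#'
#' Biomechanical-risk measure: the radius of the least-squares circle
#' (Taubin algebraic fit) through the inferior bone-contour points within
#' `window_mm` of arc length centred at the landmark. Smaller radius = more
#' peaked ischium = higher biomechanical risk. Collinear points are a
#' degenerate (flat) contour and return `Inf` with a warning rather than a
#' finite number.
#'
#' @param bone_contour Data frame of ordered contour points with columns `x`
#'   and `y` in mm (see [bone_inferior_contour()]).
#' @param landmark An `it_landmark` (its `ap_mm`/`height_mm` select the
#'   window centre); if `NULL`, the most inferior contour point is used.
#' @param window_mm Arc-length window (default 50 mm).
#' @return Radius in mm; `Inf` for a degenerate flat contour.
#' @export
sagittal_radius_of_curvature <- function(bone_contour, landmark = NULL,
                                         window_mm = 50) {
  if (!is.data.frame(bone_contour) || !all(c("x", "y") %in% names(bone_contour))) {
    abort("`bone_contour` must be a data frame with columns `x` and `y` (mm).")
  }
  pts <- arrange(as_tibble(bone_contour), .data$x)
  if (nrow(pts) < 3) abort("Need at least 3 contour points.")
  if (is.null(landmark)) {
    i0 <- which.max(pts$y)
  } else {
    i0 <- which.min((pts$x - landmark$ap_mm)^2 + (pts$y - landmark$height_mm)^2)
  }
  seg_len <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  arc <- c(0, cumsum(seg_len))
  keep <- abs(arc - arc[i0]) <= window_mm / 2
  x <- pts$x[keep]; y <- pts$y[keep]
  if (length(x) < 3) abort("Fewer than 3 contour points within the window.")
  # Collinearity check: maximal distance to the chord through the endpoints.
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  chord <- sqrt(dx^2 + dy^2)
  dev <- abs(dx * (y - y[1]) - dy * (x - x[1])) / max(chord, .Machine$double.eps)
  if (max(dev) < 1e-9 * max(chord, 1)) {
    warn("Contour points are collinear; returning an infinite radius.")
    return(Inf)
  }
  fit <- circle_fit_taubin(x, y)
  if (!is.finite(fit[3])) {
    warn("Degenerate circle fit; returning an infinite radius.")
    return(Inf)
  }
  fit[3]
}
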