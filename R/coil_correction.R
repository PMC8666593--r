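#' Fit the phantom-derived normalization curve
#'
#' Models the vertical coil-intensity falloff from a homogeneous-phantom scan.
#' The mean in-mask intensity at each image height `h` (mm above the inferior
#' edge, the coil side) is fit by least squares to the two-term power model
#'
#'   `I(h) = amplitude * (h + origin_mm)^exponent + offset`
#'
#' where `origin_mm` absorbs the true offset between the coil plane and the
#' image edge and `offset` is the baseline phantom signal. Fitting is
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) from a small multi-start grid;
#' a flat profile is detected and returned as an amplitude-zero curve rather
#' than a degenerate fit.
#'
#' Per-height means are weighted by their in-mask pixel counts (heights cut
#' near the edge of the spherical phantom average few pixels and are noisier).
#'
#' When `origin_mm` is supplied (the coil-plane offset is scanner geometry
#' and is often known), only amplitude, exponent and offset are estimated;
#' with `origin_mm = NULL` the origin is estimated too, in which case the
#' four parameters are only jointly identified at moderate noise — the fitted
#' curve stays accurate but the individual coefficients trade off along a
#' ridge.
#'
#' @param phantom A [sagittal_slice()] of the homogeneous phantom, or a
#'   `phantom_scan` object from [generate_phantom_scan()] (in which case
#'   `mask` defaults to its mask).
#' @param mask Logical matrix marking the homogeneous region.
#' @param origin_mm Known height offset of the coil plane below the inferior
#'   image edge, or `NULL` (default) to estimate it.
#' @return An object of class `normalization_curve`: `amplitude`, `exponent`,
#'   `origin_mm`, `offset`, `fit_residual_rms`, `spacing_mm`, `n_heights`,
#'   and `profile` (tibble of per-height means used in the fit).
#' @examples
#' ph <- generate_phantom_scan(c(3000, -0.5), noise_sd = 0, seed = 1)
#' curve <- fit_normalization_curve(ph)
#' tidy(curve)
#' @export
fit_normalization_curve <- function(phantom, mask = NULL, origin_mm = NULL) {
  if (inherits(phantom, "phantom_scan")) {
    mask <- mask %||% phantom$mask
    phantom <- phantom$slice
  }
  stopifnot(is_sagittal_slice(phantom))
  if (is.null(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(phantom$intensity))) {
    abort("`mask` must be a logical matrix with the slice's dimensions.")
  }
  if (!any(mask)) abort("`mask` is empty.")
  heights <- coil_height_mm(phantom)
  rows_in <- which(rowSums(mask) > 0)
  if (length(rows_in) < 10) {
    abort("Mask spans fewer than 10 distinct heights; cannot fit a curve.")
  }
  profile <- tibble(
    height_mm = heights[rows_in],
    mean_intensity = vapply(rows_in, function(r) {
      mean(phantom$intensity[r, mask[r, ]])
    }, numeric(1)),
    n_px = rowSums(mask)[rows_in]
  )

  h <- profile$height_mm
  m <- profile$mean_intensity
  w <- as.numeric(profile$n_px)
  rng <- max(m) - min(m)
  if (rng < 1e-8 * max(1, abs(mean(m)))) {
    # Flat field: no resolvable gradient.
    return(new_normalization_curve(0, 0, origin_mm %||% 10, mean(m),
                                   sqrt(mean((m - mean(m))^2)),
                                   phantom$spacing_mm, profile))
  }

  best <- NULL
  y0_grid <- if (is.null(origin_mm)) c(2, 5, 10, 20, 50) else origin_mm
  for (y0 in y0_grid) {
    for (b0 in c(-0.3, -0.5, -1)) {
      # Seed (a, c) by weighted linear least squares given (y0, b0).
      basis <- (h + y0)^b0
      ls <- stats::lm.wfit(cbind(basis, 1), m, w)
      a0 <- unname(ls$coefficients[1]); c0 <- unname(ls$coefficients[2])
      fit <- tryCatch({
        if (is.null(origin_mm)) {
          minpack.lm::nlsLM(
            m ~ a * (h + y0f)^b + c0f,
            start = list(a = a0, b = b0, y0f = y0, c0f = c0),
            lower = c(a = -Inf, b = -10, y0f = 0.1, c0f = -Inf),
            upper = c(a = Inf, b = 10, y0f = 1e4, c0f = Inf),
            weights = w,
            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          minpack.lm::nlsLM(
            m ~ a * (h + y0)^b + c0f,
            start = list(a = a0, b = b0, c0f = c0),
            lower = c(a = -Inf, b = -10, c0f = -Inf),
            weights = w,
            control = minpack.lm::nls.lm.control(maxiter = 200))
        }
      }, error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(w * residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort(paste0("Normalization-curve fit failed to converge from every start; ",
                 "profile range ", signif(rng, 4), "."))
  }
  cf <- coef(best$fit)
  fitted_y0 <- if (is.null(origin_mm)) cf[["y0f"]] else origin_mm
  rms <- sqrt(sum(residuals(best$fit)^2) / length(m))
  # Finite over the whole image height by construction (origin_mm > 0).
  new_normalization_curve(cf[["a"]], cf[["b"]], fitted_y0, cf[["c0f"]],
                          rms, phantom$spacing_mm, profile)
}

new_normalization_curve <- function(amplitude, exponent, origin_mm, offset,
                                    rms, spacing_mm, profile) {
  structure(list(amplitude = unname(amplitude), exponent = unname(exponent),
                 origin_mm = unname(origin_mm), offset = unname(offset),
                 fit_residual_rms = unname(rms), spacing_mm = spacing_mm,
                 profile = profile),
            class = "normalization_curve")
}

#' @export
print.normalization_curve <- function(x, ...) {
  cat(sprintf(
    "<normalization_curve> I(h) = %.4g * (h + %.4g)^%.4g + %.4g  (rms %.4g)\n",
    x$amplitude, x$origin_mm, x$exponent, x$offset, x$fit_residual_rms))
  invisible(x)
}

#' Evaluate a normalization curve at given heights
#'
#' @param curve A `normalization_curve`.
#' @param height_mm Heights above the inferior image edge, in mm.
#' @return Numeric vector of curve values (intensity units).
#' @export
evaluate_curve <- function(curve, height_mm) {
  curve$amplitude * (height_mm + curve$origin_mm)^curve$exponent + curve$offset
}

#' @exportS3Method generics::tidy
tidy.normalization_curve <- function(x, ...) {
  tibble(term = c("amplitude", "exponent", "origin_mm", "offset"),
         estimate = c(x$amplitude, x$exponent, x$origin_mm, x$offset))
}

#' @exportS3Method generics::glance
glance.normalization_curve <- function(x, ...) {
  tibble(fit_residual_rms = x$fit_residual_rms,
         n_heights = nrow(x$profile), spacing_mm = x$spacing_mm)
}

#' Correct a slice for the vertical coil gradient
#'
#' Subtracts the normalization curve evaluated at each pixel's height, then
#' adds back the curve's image-height mean so the overall brightness scale is
#' preserved (the add-back is a global constant, to which all downstream
#' effect sizes are invariant). Deterministic.
#'
#' @param slice A [sagittal_slice()].
#' @param curve A `normalization_curve` from [fit_normalization_curve()], fit
#'   at the same pixel spacing and axis convention.
#' @return A corrected [sagittal_slice()].
#' @export
correct_slice <- function(slice, curve) {
  stopifnot(is_sagittal_slice(slice), inherits(curve, "normalization_curve"))
  if (abs(slice$spacing_mm - curve$spacing_mm) > 1e-9) {
    abort("Slice and curve pixel spacings differ; refusing to correct.")
  }
  prof <- evaluate_curve(curve, coil_height_mm(slice))
  if (any(!is.finite(prof))) {
    abort("Curve is not finite over the slice height.")
  }
  corr <- slice$intensity - matrix(prof, nrow(slice$intensity),
                                   ncol(slice$intensity)) + mean(prof)
  sagittal_slice(corr, slice$spacing_mm)
}
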