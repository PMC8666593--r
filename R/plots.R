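#' Plot a sagittal slice, optionally with segmentation overlay
#'
#' @param object A [sagittal_slice()].
#' @param seg Optional [segmentation_set()] whose compartment outlines are
#'   overlaid.
#' @param landmark Optional `it_landmark` drawn as a point.
#' @param ... Unused.
#' @return A ggplot object (anterior left, superior top).
#' @exportS3Method ggplot2::autoplot
autoplot.sagittal_slice <- function(object, seg = NULL, landmark = NULL, ...) {
  px <- slice_pixels(object)
  p <- ggplot(px, aes(x = .data$col_mm, y = .data$row_mm)) +
    geom_raster(aes(fill = .data$intensity)) +
    scale_fill_gradient(low = "black", high = "white", name = "intensity") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "anterior → posterior (mm)", y = "inferior ← superior (mm)") +
    theme_minimal()
  if (!is.null(seg)) {
    sp <- seg$spacing_mm
    overlay <- bind_rows(
      mask_pixels(seg$ischium, sp, region = "ischium"),
      mask_pixels(seg$gluteus, sp, region = "gluteus"),
      mask_pixels(seg$subqf, sp, region = "subqf"))
    p <- p + geom_tile(data = overlay,
                       aes(colour = .data$region), fill = NA,
                       linewidth = 0.05, alpha = 0.3, show.legend = TRUE) +
      scale_colour_manual(values = c(ischium = "#E69F00", gluteus = "#D55E00",
                                     subqf = "#56B4E9"), name = "compartment")
  }
  if (!is.null(landmark)) {
    p <- p + annotate("point", x = landmark$ap_mm, y = landmark$height_mm,
                      colour = "red", size = 2)
  }
  p
}

#' Plot the phantom intensity profile and fitted normalization curve
#'
#' @param object A `normalization_curve` from [fit_normalization_curve()].
#' @param ... Unused.
#' @return A ggplot of per-height mean in-mask intensity with the fitted
#'   power curve.
#' @exportS3Method ggplot2::autoplot
autoplot.normalization_curve <- function(object, ...) {
  prof <- object$profile
  if (nrow(prof) == 0) abort("Curve carries no profile data to plot.")
  prof$fitted <- evaluate_curve(object, prof$height_mm)
  ggplot(prof, aes(x = .data$height_mm)) +
    geom_point(aes(y = .data$mean_intensity), size = 0.8, alpha = 0.7) +
    geom_line(aes(y = .data$fitted), colour = "#D55E00", linewidth = 0.8) +
    labs(x = "height above coil plane (mm)", y = "mean in-mask intensity",
         title = sprintf("I(h) = %.3g (h + %.3g)^%.3g + %.3g",
                         object$amplitude, object$origin_mm,
                         object$exponent, object$offset)) +
    theme_minimal()
}

#' Plot a two-group comparison as means with confidence intervals
#'
#' @param object A `group_comparison` from [group_compare()].
#' @param ... Unused.
#' @return A ggplot of per-group means with pooled-variance CI error bars.
#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  g <- object$groups
  se <- g$sd / sqrt(g$n)
  tcrit <- stats::qt(1 - (1 - object$conf.level) / 2, g$n - 1)
  g$lo <- g$mean - tcrit * se
  g$hi <- g$mean + tcrit * se
  ggplot(g, aes(x = factor(.data$level), y = .data$mean)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.15) +
    labs(x = object$group, y = object$metric,
         subtitle = sprintf("difference %.3g [%.3g, %.3g], p = %.3g",
                            object$difference, object$conf.low,
                            object$conf.high, object$p.value)) +
    theme_minimal()
}
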