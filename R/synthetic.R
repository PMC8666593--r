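#' Generative parameters for one synthetic subject
#'
#' Collects every dial of the single-subject generator. Defaults are
#' calibrated to the intensity and geometry scales of a seated-buttock
#' T1-weighted cohort: compartment means around 2000 (fat), 1320 (gluteus
#' muscle) and 400 (bone) arbitrary units, a vertical power-law coil falloff,
#' and a mid-cohort subject (moderate subcutaneous darkening under the
#' ischium, ~40% gluteal fat infiltration, 14.8 mm mean tissue depth, 83.7 mm
#' ischial radius).
#'
#' @param subqf_contrast Target standardized darkening of the adipose under
#'   the ischium relative to the surrounding adipose (unitless, on the scale
#'   of the SubQF effect-size statistic; positive = darker under the ischium).
#' @param imat_fraction Fraction of gluteus-maximus pixels assigned an
#'   adipose-like intensity (0-1).
#' @param tissue_thickness_mm Ground-truth mean soft-tissue depth under the
#'   ischial tuberosity over the 50-mm thickness window (mm, > 0).
#' @param it_radius_mm Ground-truth radius of the circular inferior bone
#'   contour of the ischium (mm, > 0).
#' @param base_intensities Named numeric vector `c(fat=, muscle=, bone=,
#'   background=)` of compartment mean intensities; must satisfy
#'   fat > muscle > bone.
#' @param texture_sd Named numeric vector of within-compartment intensity SDs
#'   (biological texture, present even in a "noiseless" scan).
#' @param imat_brightness Multiplier on the fat mean for infiltrated gluteus
#'   pixels; > 1 makes a fully infiltrated muscle brighter than the
#'   subcutaneous reference, so the IMAT effect size goes negative.
#' @param noise_sd Additive Gaussian scanner-noise SD, applied last.
#' @param gradient Coil-gradient spec `c(amplitude, exponent, origin_mm)`;
#'   the additive falloff is `amplitude * (height + origin_mm)^exponent` with
#'   height measured in mm above the inferior image edge. `origin_mm`
#'   defaults to 10 if omitted.
#' @param shape Image dimensions `c(rows, cols)` in pixels.
#' @param spacing_mm Pixel spacing in mm.
#' @param covariates Named list of subject covariates (pri_history,
#'   ischial_pri, spasms, years_wheelchair, bmi, hip_breadth_in); purely
#'   carried through to the cohort table.
#' @param seed Integer seed; all randomness in the subject flows from it.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subqf_contrast = 0.4,
                           imat_fraction = 0.4,
                           tissue_thickness_mm = 14.8,
                           it_radius_mm = 83.7,
                           base_intensities = c(fat = 2000, muscle = 1320,
                                                bone = 400, background = 60),
                           texture_sd = c(fat = 500, muscle = 380,
                                          bone = 150, background = 30),
                           imat_brightness = 1.15,
                           noise_sd = 50,
                           gradient = c(amplitude = 3000, exponent = -0.5,
                                        origin_mm = 10),
                           shape = c(176L, 256L),
                           spacing_mm = 1,
                           covariates = list(),
                           seed = 1L) {
  gradient <- normalize_gradient(gradient)
  p <- structure(list(
    subqf_contrast = subqf_contrast, imat_fraction = imat_fraction,
    tissue_thickness_mm = tissue_thickness_mm, it_radius_mm = it_radius_mm,
    base_intensities = base_intensities, texture_sd = texture_sd,
    imat_brightness = imat_brightness, noise_sd = noise_sd,
    gradient = gradient, shape = as.integer(shape),
    spacing_mm = spacing_mm, covariates = covariates,
    seed = as.integer(seed)), class = "subject_params")
  validate_subject_params(p)
  p
}

normalize_gradient <- function(gradient) {
  if (!is.numeric(gradient) || !(length(gradient) %in% c(2L, 3L))) {
    abort("`gradient` must be numeric of length 2 or 3: (amplitude, exponent[, origin_mm]).")
  }
  g <- c(gradient, if (length(gradient) == 2L) 10)
  names(g) <- c("amplitude", "exponent", "origin_mm")
  if (g[["origin_mm"]] <= 0) abort("Gradient `origin_mm` must be > 0.")
  g
}

validate_subject_params <- function(p) {
  if (p$imat_fraction < 0 || p$imat_fraction > 1) {
    abort("`imat_fraction` must lie in [0, 1].")
  }
  if (p$tissue_thickness_mm <= 0) abort("`tissue_thickness_mm` must be > 0.")
  if (p$it_radius_mm <= 0) abort("`it_radius_mm` must be > 0.")
  if (p$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  b <- p$base_intensities
  need <- c("fat", "muscle", "bone", "background")
  if (!all(need %in% names(b))) {
    abort("`base_intensities` must name fat, muscle, bone and background.")
  }
  if (!(b[["fat"]] > b[["muscle"]] && b[["muscle"]] > b[["bone"]])) {
    abort("Compartment intensities must be ordered fat > muscle > bone.")
  }
  if (any(p$texture_sd < 0)) abort("`texture_sd` values must be >= 0.")
  if (length(p$shape) != 2L || any(p$shape < 64L)) {
    abort("`shape` must be two pixel counts, each >= 64.")
  }
  invisible(p)
}

# Additive coil falloff evaluated over every image row (same for all columns).
gradient_profile <- function(gradient, n_rows, spacing_mm) {
  h <- (n_rows - seq_len(n_rows)) * spacing_mm
  gradient[["amplitude"]] * (h + gradient[["origin_mm"]])^gradient[["exponent"]]
}

gradient_field_matrix <- function(gradient, shape, spacing_mm) {
  matrix(gradient_profile(gradient, shape[1], spacing_mm),
         nrow = shape[1], ncol = shape[2])
}

#' Generate a homogeneous-phantom calibration scan
#'
#' Emulates the control scan of a homogeneous fluid-filled ball placed on the
#' planar receiver coil: a circular region of uniform base intensity,
#' modulated by the vertical power-law coil falloff and additive Gaussian
#' noise. The circular mask marks the homogeneous region used for curve
#' fitting.
#'
#' @param gradient Gradient spec `c(amplitude, exponent[, origin_mm])`, as in
#'   [subject_params()].
#' @param base_intensity Mean in-mask intensity before falloff (> 0).
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param shape Image dimensions `c(rows, cols)` in pixels.
#' @param spacing_mm Pixel spacing in mm.
#' @param seed Integer seed.
#' @return An object of class `phantom_scan`: list with `slice`
#'   ([sagittal_slice()]), logical `mask`, and the generating `gradient`,
#'   `base_intensity` and `seed`.
#' @examples
#' ph <- generate_phantom_scan(c(3000, -0.5), noise_sd = 0, seed = 1)
#' range(ph$slice$intensity[ph$mask])
#' @export
generate_phantom_scan <- function(gradient = c(3000, -0.5, 10),
                                  base_intensity = 1800,
                                  noise_sd = 0,
                                  shape = c(192L, 192L),
                                  spacing_mm = 1,
                                  seed = 1L) {
  gradient <- normalize_gradient(gradient)
  if (base_intensity <= 0) abort("`base_intensity` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  radius_px <- 0.4 * min(nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- (rows - cr)^2 + (cols - cc)^2 <= radius_px^2
  grad <- gradient_field_matrix(gradient, c(nr, nc), spacing_mm)
  if (any(base_intensity + grad[mask] <= 0)) {
    abort("Gradient drives in-mask intensity non-positive; reduce |amplitude|.")
  }
  set.seed(seed)
  img <- matrix(0.02 * base_intensity, nr, nc)
  img[mask] <- base_intensity
  img <- img + grad
  if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  structure(list(slice = sagittal_slice(img, spacing_mm), mask = mask,
                 gradient = gradient, base_intensity = base_intensity,
                 seed = as.integer(seed)),
            class = "phantom_scan")
}

#' Generate one synthetic seated-buttock slice with ground truth
#'
#' Builds a sagittal slice containing (superior to inferior, posterior block):
#' an ischium shell whose inferior contour is a circular arc of radius
#' `it_radius_mm` with a unique most-inferior peak; a gluteus maximus block
#' posterior/superior to that peak; and a subcutaneous fat layer (skin
#' included as its outermost two pixel rows) that runs under the bone and
#' gluteus down to a flat cushion plane, so the mean soft-tissue depth over
#' the 50-mm window equals `tissue_thickness_mm` up to pixel quantization.
#'
#' Intensities are drawn per compartment (Gaussian texture), a fraction
#' `imat_fraction` of gluteus pixels is re-drawn from a bright adipose-like
#' distribution, and the adipose under the ischium is shifted by exactly the
#' amount that makes the extracted-region SubQF statistic equal
#' `subqf_contrast` on the noiseless, gradient-free image. The coil gradient
#' and scanner noise are applied last.
#'
#' @param params A [subject_params()] object.
#' @return A list of class `synthetic_subject` with elements `slice`
#'   ([sagittal_slice()]), `seg` ([segmentation_set()]), and `truth` (class
#'   `subject_truth`): the parameters, exact compartment masks (`skin` and
#'   infiltrated-pixel indices included), the landmark, the pre-gradient
#'   noise-free image, the applied gradient field, and the under/surrounding
#'   pixel index sets used for calibration.
#' @examples
#' sub <- generate_subject_slice(subject_params(noise_sd = 0, seed = 7))
#' sub$seg
#' @export
generate_subject_slice <- function(params) {
  validate_subject_params(params)
  s <- params$spacing_mm
  H <- params$shape[1]; W <- params$shape[2]
  R <- params$it_radius_mm
  px <- function(mm) max(1L, as.integer(round(mm / s)))

  c0 <- as.integer(round(0.46 * W))
  peak_row <- H - px(40)
  w_bone <- floor(min(35, R - 5) / s)
  if (w_bone < 2) abort("Generation error: ischial radius too small for the bone shell.")
  t_bone <- max(3L, px(12))

  bone <- matrix(FALSE, H, W)
  cols_bone <- (c0 - w_bone):(c0 + w_bone)
  if (min(cols_bone) < 2 || max(cols_bone) > W - 1) {
    abort("Generation error: bone extends outside the image.")
  }
  b_bottom <- integer(W)  # 0 = no bone in column
  for (c in cols_bone) {
    d_mm <- (c - c0) * s
    drop_mm <- R - sqrt(R^2 - d_mm^2)
    b <- peak_row - as.integer(round(drop_mm / s))
    top <- max(1L, b - t_bone + 1L)
    bone[top:b, c] <- TRUE
    b_bottom[c] <- b
  }

  # Flat cushion plane chosen so the mean depth over the 50-mm window is the
  # requested thickness (up to rounding).
  half_win <- floor(25 / s)
  win_cols <- max(c0 - half_win, min(cols_bone)):min(c0 + half_win, max(cols_bone))
  row_bottom <- as.integer(round(mean(b_bottom[win_cols]) +
                                   params$tissue_thickness_mm / s))
  if (row_bottom > H - 2L) abort("Generation error: tissue extends below the image.")
  if (row_bottom < peak_row + 2L) {
    abort("Generation error: tissue too thin, bone reaches the skin surface.")
  }

  gluteus <- matrix(FALSE, H, W)
  c_gl <- (c0 + px(6)):min(c0 + px(95), W - px(10))
  g_bot_base <- row_bottom - px(14)
  g_top <- max(2L, g_bot_base - px(42))
  for (c in c_gl) {
    g_bot <- if (b_bottom[c] > 0L) min(g_bot_base, b_bottom[c] - t_bone) else g_bot_base
    if (g_bot >= g_top) gluteus[g_top:g_bot, c] <- TRUE
  }

  subqf <- matrix(FALSE, H, W)
  c_sq <- (c0 - px(58)):min(c0 + px(88), W - px(12))
  if (min(c_sq) < 2L) abort("Generation error: SubQF extends outside the image.")
  for (c in c_sq) {
    top <- if (b_bottom[c] > 0L) {
      b_bottom[c] + 1L
    } else if (any(gluteus[, c])) {
      g_bot_base + 1L
    } else {
      row_bottom - px(20) + 1L
    }
    if (top <= row_bottom) subqf[top:row_bottom, c] <- TRUE
  }
  skin <- matrix(FALSE, H, W)
  skin[(row_bottom - 1L):row_bottom, ] <- subqf[(row_bottom - 1L):row_bottom, ]

  for (nm in c("bone", "gluteus", "subqf")) {
    if (!any(get(nm))) abort(sprintf("Generation error: region '%s' is empty.", nm))
  }

  seg <- segmentation_set(ischium = bone, gluteus = gluteus, subqf = subqf,
                          spacing_mm = s)

  # ---- intensities -------------------------------------------------------
  set.seed(params$seed)
  base <- params$base_intensities; tsd <- params$texture_sd
  other_mean <- (base[["fat"]] + base[["muscle"]]) / 2
  other_sd <- (tsd[["fat"]] + tsd[["muscle"]]) / 2
  img <- matrix(rnorm(H * W, base[["background"]], tsd[["background"]]), H, W)
  body <- matrix(FALSE, H, W)
  body_cols <- min(c_sq):max(c(c_sq, c_gl))
  body[seq_len(row_bottom), body_cols] <- TRUE
  other <- body & !(bone | gluteus | subqf)
  img[other] <- rnorm(sum(other), other_mean, other_sd)
  img[bone] <- rnorm(sum(bone), base[["bone"]], tsd[["bone"]])
  img[gluteus] <- rnorm(sum(gluteus), base[["muscle"]], tsd[["muscle"]])
  img[subqf] <- rnorm(sum(subqf), base[["fat"]], tsd[["fat"]])

  glut_idx <- which(gluteus)
  n_inf <- round(params$imat_fraction * length(glut_idx))
  infiltrated <- if (n_inf > 0) sample(glut_idx, n_inf) else integer(0)
  if (n_inf > 0) {
    img[infiltrated] <- rnorm(n_inf, base[["fat"]] * params$imat_brightness,
                              tsd[["fat"]])
  }

  # ---- calibrate the under-ischium darkening -----------------------------
  slice0 <- sagittal_slice(img, s)
  landmark <- find_it_peak(seg)
  regions <- extract_subqf_regions(slice0, seg, landmark)
  under_idx <- (regions$under$col - 1L) * H + regions$under$row
  surr_idx <- (regions$surrounding$col - 1L) * H + regions$surrounding$row
  m_u <- mean(img[under_idx]); m_s <- mean(img[surr_idx])
  sd_p <- pooled_sd(img[surr_idx], img[under_idx])
  if (sd_p > 0) {
    shift <- (m_s - params$subqf_contrast * sd_p) - m_u
  } else if (abs(params$subqf_contrast) < 1e-12) {
    shift <- m_s - m_u
  } else {
    abort("Generation error: zero texture SD cannot carry a nonzero SubQF contrast.")
  }
  img[under_idx] <- img[under_idx] + shift

  pre_gradient <- img
  grad <- if (abs(params$gradient[["amplitude"]]) > 0) {
    gradient_field_matrix(params$gradient, c(H, W), s)
  } else {
    matrix(0, H, W)
  }
  img <- img + grad
  if (params$noise_sd > 0) {
    img <- img + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
  }

  truth <- structure(list(
    params = params, landmark = landmark,
    masks = list(bone = bone, gluteus = gluteus, subqf = subqf, skin = skin),
    infiltrated = infiltrated,
    under_idx = under_idx, surrounding_idx = surr_idx,
    under_shift = shift,
    pre_gradient = pre_gradient, gradient_field = grad,
    row_bottom = row_bottom, peak_row = peak_row, c0 = c0
  ), class = "subject_truth")

  structure(list(slice = sagittal_slice(img, s), seg = seg, truth = truth),
            class = "synthetic_subject")
}

#' Default per-group generative distributions for a synthetic cohort
#'
#' Two groups mirror a wheelchair-user cohort with and without pressure-injury
#' history: SubQF effect-size means 0.21 (SD 0.56) vs 0.58 (SD 0.45), mean
#' tissue thickness 17.1 (7.1) vs 12.5 (3.9) mm, sagittal radius 93.9 (44.7)
#' vs 73.6 (27.5) mm, years of wheelchair use 10.7 (9.3) vs 19.6 (13.3), BMI
#' 24.5 (5.0) vs 23.3 (4.6), compressible hip breadth 1.7 (0.8) vs 1.1 (0.8)
#' inches, spasm prevalence 0.56 vs 0.70. Gluteal infiltration fractions
#' (means 0.30 vs 0.39, SDs 0.30 vs 0.26) are calibrated through the
#' generator's measured fraction-to-effect-size mapping (approximately
#' 1.19 - 1.99 * fraction at default intensities) so the rendered IMAT
#' effect sizes centre near 0.59 vs 0.41 with SD ~0.55 and roughly a sixth
#' of subjects cross into full infiltration (negative IMAT effect size).
#' Years of use is positively correlated with the infiltration fraction
#' while spasms are associated with leaner muscle.
#'
#' @return A nested list with elements `no_pri`, `pri` (each a list of
#'   `c(mean, sd)` pairs plus `spasm_rate`) and `shared` (noise, gradient,
#'   image geometry, covariate couplings, missingness rates).
#' @export
default_group_params <- function() {
  list(
    no_pri = list(
      subqf_contrast = c(mean = 0.21, sd = 0.56),
      imat_fraction = c(mean = 0.30, sd = 0.30),
      tissue_thickness_mm = c(mean = 17.1, sd = 7.1),
      it_radius_mm = c(mean = 93.9, sd = 44.7),
      years_wheelchair = c(mean = 10.7, sd = 9.3),
      bmi = c(mean = 24.5, sd = 5.0),
      hip_breadth_in = c(mean = 1.7, sd = 0.8),
      spasm_rate = 0.56
    ),
    pri = list(
      subqf_contrast = c(mean = 0.58, sd = 0.45),
      imat_fraction = c(mean = 0.39, sd = 0.26),
      tissue_thickness_mm = c(mean = 12.5, sd = 3.9),
      it_radius_mm = c(mean = 73.6, sd = 27.5),
      years_wheelchair = c(mean = 19.6, sd = 13.3),
      bmi = c(mean = 23.3, sd = 4.6),
      hip_breadth_in = c(mean = 1.1, sd = 0.8),
      spasm_rate = 0.70
    ),
    shared = list(
      noise_sd = 50,
      gradient = c(amplitude = 3000, exponent = -0.5, origin_mm = 10),
      years_imat_cor = 0.45,
      spasm_imat_beta = -1.2,
      p_ischial_given_pri = 12 / 22,
      p_missing_spasms = 5 / 43,
      p_missing_hip = 4 / 43,
      shape = c(176L, 256L),
      spacing_mm = 1
    )
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject generative parameters from group-specific distributions
#' (see [default_group_params()]), optionally renders every subject's slice
#' and segmentation, and returns the true parameter table. All randomness
#' flows from `seed`; the same seed reproduces the cohort bit-identically.
#'
#' @param n_no_pri,n_pri Group sizes (each >= 2).
#' @param group_params Nested list as returned by [default_group_params()].
#' @param seed Integer seed.
#' @param render If `TRUE`, generate the image and masks for every subject
#'   via [generate_subject_slice()]; if `FALSE`, return only the parameter
#'   table (useful for statistical calibration studies).
#' @return A list of class `synthetic_cohort`: `truth` (tibble, one row per
#'   subject with group label, covariates and true generative parameters),
#'   `subjects` (list of `synthetic_subject` or `NULL`), `group_params`,
#'   `seed`.
#' @examples
#' coh <- generate_cohort(n_no_pri = 3, n_pri = 3, render = FALSE, seed = 2)
#' coh$truth
#' @export
generate_cohort <- function(n_no_pri = 21, n_pri = 22,
                            group_params = default_group_params(),
                            seed = 1L, render = TRUE) {
  if (n_no_pri < 2 || n_pri < 2) abort("Each group needs at least 2 subjects.")
  for (g in c("no_pri", "pri")) {
    for (nm in setdiff(names(group_params[[g]]), "spasm_rate")) {
      if (group_params[[g]][[nm]][["sd"]] < 0) {
        abort(sprintf("Degenerate distribution: %s/%s has negative SD.", g, nm))
      }
    }
  }
  sh <- group_params$shared
  n <- n_no_pri + n_pri
  groups <- rep(c(0L, 1L), c(n_no_pri, n_pri))

  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gp <- if (groups[i] == 1L) group_params$pri else group_params$no_pri
    z_imat <- rnorm(1)
    imat <- clamp(gp$imat_fraction[["mean"]] + gp$imat_fraction[["sd"]] * z_imat, 0, 1)
    contrast <- rnorm(1, gp$subqf_contrast[["mean"]], gp$subqf_contrast[["sd"]])
    thick <- clamp(rnorm(1, gp$tissue_thickness_mm[["mean"]],
                         gp$tissue_thickness_mm[["sd"]]), 5, 40)
    radius <- clamp(rnorm(1, gp$it_radius_mm[["mean"]], gp$it_radius_mm[["sd"]]),
                    42, 150)
    rho <- sh$years_imat_cor
    years <- clamp(gp$years_wheelchair[["mean"]] + gp$years_wheelchair[["sd"]] *
                     (rho * z_imat + sqrt(1 - rho^2) * rnorm(1)), 2, 60)
    bmi <- clamp(rnorm(1, gp$bmi[["mean"]], gp$bmi[["sd"]]), 14, 40)
    hip <- clamp(rnorm(1, gp$hip_breadth_in[["mean"]], gp$hip_breadth_in[["sd"]]),
                 0.2, 3.2)
    spasm <- rbinom(1, 1, plogis(qlogis(gp$spasm_rate) +
                                   sh$spasm_imat_beta * z_imat))
    ischial <- if (groups[i] == 1L) rbinom(1, 1, sh$p_ischial_given_pri) else 0L
    if (rbinom(1, 1, sh$p_missing_spasms) == 1L) spasm <- NA_integer_
    if (rbinom(1, 1, sh$p_missing_hip) == 1L) hip <- NA_real_
    rows[[i]] <- tibble(
      subject_id = sprintf("S%02d", i), pri_history = groups[i],
      ischial_pri = as.integer(ischial), spasms = as.integer(spasm),
      years_wheelchair = years, bmi = bmi, hip_breadth_in = hip,
      subqf_contrast = contrast, imat_fraction = imat,
      tissue_thickness_mm = thick, it_radius_mm = radius,
      seed = subject_seeds[i]
    )
  }
  truth <- bind_rows(rows)

  subjects <- NULL
  if (render) {
    subjects <- purrr::map(seq_len(n), function(i) {
      r <- truth[i, ]
      generate_subject_slice(subject_params(
        subqf_contrast = r$subqf_contrast, imat_fraction = r$imat_fraction,
        tissue_thickness_mm = r$tissue_thickness_mm,
        it_radius_mm = r$it_radius_mm,
        noise_sd = sh$noise_sd, gradient = sh$gradient,
        shape = sh$shape, spacing_mm = sh$spacing_mm,
        covariates = list(pri_history = r$pri_history,
                          ischial_pri = r$ischial_pri, spasms = r$spasms,
                          years_wheelchair = r$years_wheelchair, bmi = r$bmi,
                          hip_breadth_in = r$hip_breadth_in),
        seed = r$seed))
    })
    names(subjects) <- truth$subject_id
  }

  structure(list(truth = truth, subjects = subjects,
                 group_params = group_params, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d no-PrI / %d PrI), %s\n",
              nrow(x$truth), sum(x$truth$pri_history == 0),
              sum(x$truth$pri_history == 1),
              if (is.null(x$subjects)) "parameters only" else "rendered"))
  invisible(x)
}
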