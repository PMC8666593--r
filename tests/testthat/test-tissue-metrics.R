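test_that("effect size matches the pooled-SD formula on hand-checkable vectors", {
  expect_equal(effect_size(c(3, 4, 5), c(1, 2, 3)), 2.0, tolerance = 1e-12)
  # equal means -> 0 regardless of spread
  expect_equal(effect_size(c(1, 5, 9), c(4, 5, 6)), 0, tolerance = 1e-12)
  # random vectors against the independent closed form
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(sample(5:50, 1), 10, 3); b <- rnorm(sample(5:50, 1), 8, 2)
    expect_equal(effect_size(a, b), oracle_effect_size(a, b), tolerance = 1e-12)
  }
})

test_that("effect size is antisymmetric and affine-invariant", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(30, 1500, 400); b <- rnorm(25, 1200, 350)
    es <- effect_size(a, b)
    expect_equal(effect_size(b, a), -es, tolerance = 1e-12)
    s <- runif(1, 0.1, 10); o <- runif(1, -500, 500)
    expect_equal(effect_size(s * a + o, s * b + o), es, tolerance = 1e-12)
  }
})

test_that("degenerate effect-size inputs raise errors", {
  expect_error(effect_size(c(1), c(1, 2, 3)), "at least 2")
  expect_error(effect_size(c(2, 2, 2), c(2, 2)), "Pooled SD is zero")
})

test_that("adipose metrics wire the regions into the two statistics", {
  sub <- clean_subject(contrast = 0.58, seed = 3)
  lm <- find_it_peak(sub$seg)
  rg <- extract_subqf_regions(sub$slice, sub$seg, lm)
  im <- extract_imat_regions(sub$slice, sub$seg, lm)
  met <- compute_adipose_metrics(rg$under, rg$surrounding,
                                 im$ref_adipose, im$gluteus)
  expect_equal(met$subqf_effect_size, 0.58, tolerance = 1e-9)
  expect_equal(met$subqf_effect_size,
               effect_size(rg$surrounding, rg$under), tolerance = 1e-12)
  expect_equal(met$imat_effect_size,
               effect_size(im$ref_adipose, im$gluteus), tolerance = 1e-12)
  expect_equal(met$adipose_under_n, nrow(rg$under))
  expect_true(all(is.finite(unlist(met))))
})

test_that("a brighter-under-ischium subject has a negative SubQF effect size", {
  sub <- clean_subject(contrast = -0.69, seed = 23)
  rg <- extract_subqf_regions(sub$slice, sub$seg)
  expect_lt(effect_size(rg$surrounding, rg$under), 0)
})

test_that("midpoint method recovers the infiltration fraction at high contrast", {
  sub <- generate_subject_slice(subject_params(
    imat_fraction = 0.3, noise_sd = 0, gradient = c(0, -0.5),
    texture_sd = c(fat = 80, muscle = 80, bone = 50, background = 10),
    seed = 5))
  im <- extract_imat_regions(sub$slice, sub$seg)
  mp <- midpoint_imat_fraction(im$ref_adipose, im$gluteus)
  expect_false(mp$flagged)
  expect_lt(abs(mp$fraction - 0.3), 0.05)
})

test_that("midpoint method flags lean and fully infiltrated extremes sensibly", {
  lean <- generate_subject_slice(subject_params(
    imat_fraction = 0, noise_sd = 0, gradient = c(0, -0.5),
    texture_sd = c(fat = 60, muscle = 60, bone = 50, background = 10),
    seed = 8))
  im <- extract_imat_regions(lean$slice, lean$seg)
  mp <- midpoint_imat_fraction(im$ref_adipose, im$gluteus)
  expect_lt(mp$fraction, 0.02)

  full <- generate_subject_slice(subject_params(
    imat_fraction = 1, noise_sd = 0, gradient = c(0, -0.5),
    texture_sd = c(fat = 60, muscle = 60, bone = 50, background = 10),
    seed = 9))
  imf <- extract_imat_regions(full$slice, full$seg)
  expect_true(midpoint_imat_fraction(imf$ref_adipose, imf$gluteus)$flagged)
})

test_that("midpoint fraction correlates negatively with IMAT effect size mid-range", {
  vals <- t(sapply(seq(0.25, 0.6, length.out = 10), function(phi) {
    sub <- generate_subject_slice(subject_params(imat_fraction = phi,
                                                 seed = round(1e4 * phi)))
    im <- extract_imat_regions(sub$slice, sub$seg)
    c(frac = midpoint_imat_fraction(im$ref_adipose, im$gluteus)$fraction,
      es = effect_size(im$ref_adipose, im$gluteus))
  }))
  expect_lt(cor(vals[, "frac"], vals[, "es"]), 0)
})

test_that("bulk thickness is exact on slabs and recovers the generative depth", {
  expect_equal(bulk_tissue_thickness(slab_seg(rep(15L, 60))), 15.0)
  # depth varying linearly 10..20: mean over the 50-mm window at the landmark
  depths <- as.integer(round(seq(10, 20, length.out = 60)))
  seg_lin <- slab_seg(depths)
  lm_lin <- find_it_peak(seg_lin)
  in_win <- abs((seq_len(60) - 1) - lm_lin$ap_mm) <= 25
  expect_equal(bulk_tissue_thickness(seg_lin, lm_lin), mean(depths[in_win]),
               tolerance = 1e-9)
  sub <- generate_subject_slice(subject_params(tissue_thickness_mm = 12.5,
                                               noise_sd = 0,
                                               gradient = c(0, -0.5), seed = 4))
  expect_lt(abs(bulk_tissue_thickness(sub$seg) - 12.5), 0.5 + 1e-9)
  empty <- slab_seg(rep(0L, 60))
  expect_error(bulk_tissue_thickness(empty), "No tissue columns")
})

test_that("circle fit is exact on a noiseless arc and flags collinear points", {
  th <- seq(-0.5, 0.5, length.out = 40)
  arc <- tibble::tibble(x = 100 + 50 * sin(th), y = 30 + 50 * cos(th))
  expect_equal(sagittal_radius_of_curvature(arc, window_mm = 60), 50,
               tolerance = 1e-6)
  line <- tibble::tibble(x = 1:10, y = rep(2, 10))
  expect_warning(r <- sagittal_radius_of_curvature(line, window_mm = 50),
                 "collinear")
  expect_identical(r, Inf)
  expect_error(sagittal_radius_of_curvature(tibble::tibble(x = 1:2, y = 1:2)),
               "at least 3")
})

test_that("circle fit tolerates 0.2-mm jitter on an 80-mm arc", {
  radii <- sapply(1:20, function(s) {
    set.seed(s)
    th <- seq(-0.35, 0.35, length.out = 60)
    pts <- tibble::tibble(x = 80 * sin(th) + rnorm(60, 0, 0.2),
                          y = 80 * cos(th) + rnorm(60, 0, 0.2))
    sagittal_radius_of_curvature(pts, window_mm = 56)
  })
  expect_lt(abs(mean(radii) - 80), 2)
})

test_that("curvature of a synthetic subject matches the generative radius", {
  sub <- generate_subject_slice(subject_params(it_radius_mm = 83.7,
                                               noise_sd = 0,
                                               gradient = c(0, -0.5), seed = 3))
  r <- sagittal_radius_of_curvature(bone_inferior_contour(sub$seg),
                                    find_it_peak(sub$seg))
  expect_lt(abs(r - 83.7) / 83.7, 0.05)
})

test_that("geometry in mm is stable when pixel spacing doubles", {
  p1 <- subject_params(noise_sd = 0, gradient = c(0, -0.5), seed = 12)
  p2 <- subject_params(noise_sd = 0, gradient = c(0, -0.5), seed = 12,
                       shape = c(88L, 128L), spacing_mm = 2)
  s1 <- generate_subject_slice(p1); s2 <- generate_subject_slice(p2)
  t1 <- bulk_tissue_thickness(s1$seg); t2 <- bulk_tissue_thickness(s2$seg)
  expect_lt(abs(t1 - t2), 2.5)  # one coarse-grid pixel of quantization
  r1 <- sagittal_radius_of_curvature(bone_inferior_contour(s1$seg))
  r2 <- sagittal_radius_of_curvature(bone_inferior_contour(s2$seg))
  expect_lt(abs(r1 - r2) / r1, 0.15)
})

test_that("measured metrics track generative parameters with slope ~1", {
  contrasts <- seq(-0.4, 1.0, length.out = 8)
  measured <- sapply(seq_along(contrasts), function(i) {
    sub <- clean_subject(contrast = contrasts[i], seed = 300 + i)
    rg <- extract_subqf_regions(sub$slice, sub$seg)
    effect_size(rg$surrounding, rg$under)
  })
  fit <- lm(measured ~ contrasts)
  expect_lt(abs(coef(fit)[2] - 1), 0.02)
})
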