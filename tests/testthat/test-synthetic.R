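test_that("phantom with zero gradient and zero noise is flat at base intensity", {
  ph <- generate_phantom_scan(c(0, -0.5), base_intensity = 1500, noise_sd = 0,
                              seed = 1)
  expect_true(all(ph$slice$intensity[ph$mask] == 1500))
})

test_that("phantom matches the closed-form falloff pixel by pixel", {
  ph <- generate_phantom_scan(c(3000, -0.5, 10), base_intensity = 1800,
                              noise_sd = 0, seed = 1)
  h <- coil_height_mm(ph$slice)
  expected <- outer(1800 + 3000 * (h + 10)^(-0.5),
                    rep(1, ncol(ph$slice$intensity)))
  expect_equal(ph$slice$intensity[ph$mask], expected[ph$mask], tolerance = 1e-12)
})

test_that("phantom generation is bit-identical under the same seed", {
  a <- generate_phantom_scan(c(3000, -0.5), noise_sd = 40, seed = 77)
  b <- generate_phantom_scan(c(3000, -0.5), noise_sd = 40, seed = 77)
  expect_identical(a$slice$intensity, b$slice$intensity)
})

test_that("phantom rejects parameters that drive intensities non-positive", {
  expect_error(generate_phantom_scan(c(-4000, -0.1), base_intensity = 100),
               "non-positive")
  expect_error(generate_phantom_scan(c(3000, -0.5), base_intensity = -5), "> 0")
})

test_that("subject params are validated", {
  expect_error(subject_params(imat_fraction = 1.2), "\\[0, 1\\]")
  expect_error(subject_params(tissue_thickness_mm = -1), "> 0")
  expect_error(subject_params(noise_sd = -1), ">= 0")
  expect_error(subject_params(base_intensities = c(fat = 100, muscle = 200,
                                                   bone = 50, background = 10)),
               "fat > muscle > bone")
})

test_that("compartment masks are disjoint, nonempty, and skin stays inside SubQF", {
  sub <- clean_subject(seed = 11)
  m <- sub$truth$masks
  expect_true(all(sapply(m[c("bone", "gluteus", "subqf")], sum) > 0))
  expect_false(any(m$bone & m$gluteus))
  expect_false(any(m$bone & m$subqf))
  expect_false(any(m$gluteus & m$subqf))
  expect_true(all(m$subqf[m$skin]))
  expect_identical(sub$seg$ischium, m$bone)
})

test_that("stored gradient field reproduces the noiseless image exactly", {
  sub <- generate_subject_slice(subject_params(noise_sd = 0, seed = 9))
  expect_equal(sub$truth$pre_gradient + sub$truth$gradient_field,
               sub$slice$intensity, tolerance = 1e-12)
})

test_that("noiseless measurement on ground-truth regions returns the generative contrast", {
  for (target in c(0, 0.58, -0.69)) {
    sub <- clean_subject(contrast = target, seed = 21)
    rg <- extract_subqf_regions(sub$slice, sub$seg)
    expect_equal(effect_size(rg$surrounding, rg$under), target,
                 tolerance = 1e-9)
  }
})

test_that("full gluteal infiltration yields a negative IMAT effect size", {
  sub <- generate_subject_slice(subject_params(imat_fraction = 1, noise_sd = 0,
                                               gradient = c(0, -0.5), seed = 6))
  im <- extract_imat_regions(sub$slice, sub$seg)
  expect_lt(effect_size(im$ref_adipose, im$gluteus), 0)
})

test_that("IMAT effect size decreases monotonically with the infiltration fraction", {
  es <- sapply(c(0, 0.3, 0.6, 1), function(phi) {
    sub <- generate_subject_slice(subject_params(imat_fraction = phi,
                                                 noise_sd = 0,
                                                 gradient = c(0, -0.5),
                                                 seed = 31))
    im <- extract_imat_regions(sub$slice, sub$seg)
    effect_size(im$ref_adipose, im$gluteus)
  })
  expect_true(all(diff(es) < 0))
})

test_that("Monte-Carlo SubQF recovery at default noise is unbiased within 0.1", {
  cv <- fit_normalization_curve(default_phantom(noise_sd = 10, seed = 99))
  measured <- sapply(1:50, function(s) {
    sub <- generate_subject_slice(subject_params(subqf_contrast = 0.58,
                                                 seed = 1000 + s))
    rg <- extract_subqf_regions(correct_slice(sub$slice, cv), sub$seg)
    effect_size(rg$surrounding, rg$under)
  })
  expect_lt(abs(mean(measured) - 0.58), 0.1)
})

test_that("cohort honours requested group sizes and reproduces under a seed", {
  coh <- generate_cohort(n_no_pri = 21, n_pri = 22, seed = 5, render = FALSE)
  expect_equal(nrow(coh$truth), 43)
  expect_equal(sum(coh$truth$pri_history == 0), 21)
  expect_equal(sum(coh$truth$pri_history == 1), 22)
  expect_true(all(!duplicated(coh$truth$subject_id)))
  coh2 <- generate_cohort(n_no_pri = 21, n_pri = 22, seed = 5, render = FALSE)
  expect_identical(coh$truth, coh2$truth)
})

test_that("cohort rejects degenerate distribution parameters", {
  gp <- default_group_params()
  gp$pri$subqf_contrast[["sd"]] <- -0.1
  expect_error(generate_cohort(group_params = gp, render = FALSE),
               "Degenerate")
  expect_error(generate_cohort(n_no_pri = 1, n_pri = 5, render = FALSE),
               "at least 2")
})

test_that("rendered subjects reproduce bit-identically from the truth-table seed", {
  coh <- generate_cohort(n_no_pri = 2, n_pri = 2, seed = 8, render = TRUE)
  r <- coh$truth[3, ]
  again <- generate_subject_slice(subject_params(
    subqf_contrast = r$subqf_contrast, imat_fraction = r$imat_fraction,
    tissue_thickness_mm = r$tissue_thickness_mm, it_radius_mm = r$it_radius_mm,
    noise_sd = coh$group_params$shared$noise_sd,
    gradient = coh$group_params$shared$gradient, seed = r$seed))
  expect_identical(coh$subjects[[3]]$slice$intensity, again$slice$intensity)
})
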