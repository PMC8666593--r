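# Shared fixtures built in code. Heavier objects are created once per test
# run and memoised.

local_fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = local_fixture_env)) {
    assign(name, force(expr), envir = local_fixture_env)
  }
  get(name, envir = local_fixture_env)
}

# A noiseless, gradient-free subject: every measurement should round-trip
# its generative parameters exactly (up to pixel quantization for geometry).
clean_subject <- function(contrast = 0.58, seed = 3, ...) {
  generate_subject_slice(subject_params(
    subqf_contrast = contrast, noise_sd = 0,
    gradient = c(0, -0.5, 10), seed = seed, ...))
}

default_phantom <- function(noise_sd = 0, seed = 1) {
  generate_phantom_scan(c(3000, -0.5, 10), noise_sd = noise_sd, seed = seed)
}

# Tiny hand-built segmentation: flat 3-px-wide bone slab over a uniform
# 15-px soft slab, for thickness and ROI toy cases.
slab_seg <- function(depths = rep(15L, 60), bone_row = 20L,
                     H = 60L, W = 60L, spacing_mm = 1) {
  stopifnot(length(depths) == W)
  bone <- matrix(FALSE, H, W); soft <- matrix(FALSE, H, W)
  for (c in seq_len(W)) {
    bone[(bone_row - 2L):bone_row, c] <- TRUE
    if (depths[c] > 0) soft[(bone_row + 1L):(bone_row + depths[c]), c] <- TRUE
  }
  segmentation_set(ischium = bone, gluteus = matrix(FALSE, H, W),
                   subqf = soft, spacing_mm = spacing_mm)
}
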