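# Independent brute-force oracles: plain loops over pixels evaluating the
# region predicates directly, and hand ANOVA decomposition. These deliberately
# share no code with the package implementation.

oracle_subqf_split <- function(seg, landmark, margin_mm = 5, band_mm = 10) {
  sp <- seg$spacing_mm
  H <- nrow(seg$subqf); W <- ncol(seg$subqf)
  lm_mm <- (landmark$row - 1) * sp
  thr <- lm_mm - band_mm

  # ischium AP footprint within the band's height range
  fmin <- Inf; fmax <- -Inf
  for (r in 1:H) for (c in 1:W) {
    if (seg$ischium[r, c] && (r - 1) * sp >= thr) {
      fmin <- min(fmin, (c - 1) * sp); fmax <- max(fmax, (c - 1) * sp)
    }
  }
  under <- matrix(FALSE, H, W); surrounding <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (!seg$subqf[r, c]) next
    if ((r - 1) * sp < thr) next
    cm <- (c - 1) * sp
    if (cm >= fmin - margin_mm && cm <= fmax + margin_mm) {
      under[r, c] <- TRUE
    } else {
      surrounding[r, c] <- TRUE
    }
  }
  list(under = under, surrounding = surrounding)
}

oracle_imat_ref <- function(seg, landmark) {
  sp <- seg$spacing_mm
  H <- nrow(seg$subqf); W <- ncol(seg$subqf)
  g_bot <- rep(0L, W)
  for (c in 1:W) for (r in 1:H) if (seg$gluteus[r, c]) g_bot[c] <- r
  g_global <- max(g_bot)
  ref <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (!seg$subqf[r, c]) next
    if (!((c - 1) * sp > (landmark$col - 1) * sp)) next
    bound <- if (g_bot[c] > 0L) g_bot[c] else g_global
    if (r > bound) ref[r, c] <- TRUE
  }
  ref
}

# Region tibble -> logical mask, for comparison against oracle masks.
region_to_mask <- function(region, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[cbind(region$row, region$col)] <- TRUE
  m
}

oracle_anova_two_groups <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2); n <- n1 + n2
  grand <- mean(c(y1, y2))
  ssb <- n1 * (mean(y1) - grand)^2 + n2 * (mean(y2) - grand)^2
  ssw <- sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  list(F = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# Closed-form pooled-SD effect size for hand checks.
oracle_effect_size <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
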