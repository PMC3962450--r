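# Shared fixtures and independent oracles used across the test files.

# Random positive-definite tensor with eigenvalues in a physiological
# diffusivity range (mm^2/s), drawn from the current RNG state.
random_pd_tensor <- function(lam_range = c(0.2e-3, 2e-3)) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  lam <- sort(runif(3, lam_range[1], lam_range[2]), decreasing = TRUE)
  Q %*% diag(lam) %*% t(Q)
}

tensor_to_d6 <- function(D) {
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# Random 3D rotation matrix.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Independent variance-component oracle: one-way random-effects ANOVA via
# stats::aov mean squares, nothing shared with the package implementation.
aov_vc_oracle <- function(x) {
  df <- data.frame(value = c(x[, 1], x[, 2]),
                   subject = factor(rep(seq_len(nrow(x)), 2)))
  tab <- anova(stats::aov(value ~ subject, data = df))
  msb <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  list(var_between = max(0, (msb - msw) / 2), var_within = msw,
       msb = msb, msw = msw)
}

# Compact phantom used where full desk scale is unnecessary: two regions
# (one anisotropic slab, one near-isotropic sphere) in a 10x10x6 grid.
small_region_spec <- function() {
  data.frame(
    label_id = 1:2,
    region_name = c("white_slab", "grey_ball"),
    shape = c("box", "sphere"),
    cx = c(NA, 6), cy = c(NA, 6), cz = c(NA, 1), radius = c(NA, 1.5),
    x0 = c(1, NA), x1 = c(8, NA), y0 = c(1, NA), y1 = c(8, NA),
    z0 = c(3, NA), z1 = c(4, NA),
    l1 = c(1.6e-3, 0.85e-3), l2 = c(0.35e-3, 0.65e-3),
    l3 = c(0.30e-3, 0.60e-3),
    dx = c(1, 1), dy = c(0, 0), dz = c(0, 0),
    fa_thresholded = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
}

small_phantom <- function(...) {
  phantom_config(grid_shape = c(10L, 10L, 6L),
                 region_spec = small_region_spec(), ...)
}
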