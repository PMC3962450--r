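sch42 <- default_scheme(42, 7, 1000)

test_that("log-linear fit inverts noise-free signals exactly", {
  set.seed(11)
  for (i in 1:50) {
    D <- random_pd_tensor()
    d6 <- tensor_to_d6(D)
    s <- predict_signal(D, 100, sch42)
    fit <- fit_loglinear(s, sch42)
    expect_lt(max(abs(fit$d - d6)) / max(abs(d6)), 1e-9)
    expect_equal(fit$s0_est, 100, tolerance = 1e-9)
  }

  # Constant signals: zero tensor, s0 equals the constant.
  fit0 <- fit_loglinear(rep(80, length(sch42$bvals)), sch42)
  expect_equal(unname(fit0$d), rep(0, 6), tolerance = 1e-12)
  expect_equal(fit0$s0_est, 80, tolerance = 1e-12)

  sch6 <- acquisition_scheme(c(0, rep(1000, 5)),
                             rbind(0, diag(3), matrix(c(1, 1, 0, 1, 0, 1) /
                                                        sqrt(2), 2, 3, TRUE)))
  expect_error(fit_loglinear(rep(1, 6), sch6), "at least 7")

  # Degenerate direction set (all gradients collinear): rank deficient.
  schdeg <- acquisition_scheme(c(0, rep(1000, 8)),
                               rbind(0, matrix(rep(c(1, 0, 0), 8), 8, 3,
                                               byrow = TRUE)))
  expect_error(fit_loglinear(rep(1, 9), schdeg), "degenerate|rank")
})

test_that("nonlinear fit refines without ever worsening the objective", {
  set.seed(12)
  D <- random_pd_tensor()
  s <- predict_signal(D, 100, sch42)
  init <- fit_loglinear(s, sch42)
  fit <- fit_nlls(s, sch42, init)
  expect_lt(max(abs(fit$d - tensor_to_d6(D))) / max(abs(D)), 1e-8)
  expect_lt(fit$residual_sse, 1e-18)
  expect_lte(fit$residual_sse, init$residual_sse)
  expect_true(fit$converged)

  # Refinement property under noise: NLLS objective never exceeds the
  # log-linear initializer's objective.
  for (i in 1:30) {
    D <- random_pd_tensor()
    s <- add_rician_noise(predict_signal(D, 100, sch42), 2)
    init <- fit_loglinear(s, sch42)
    fit <- fit_nlls(s, sch42, init)
    expect_lte(fit$residual_sse, init$residual_sse)
  }

  expect_error(fit_nlls(c(NaN, rep(1, 48)), sch42), "non-finite")
})

test_that("eigendecomposition is sorted, sign-fixed and reconstructs the tensor", {
  e <- eigensystem(diag(2e-3, 3))
  expect_equal(e$values, rep(2e-3, 3))

  e <- eigensystem(diag(c(3, 2, 1) * 1e-3))
  expect_equal(e$values, c(3, 2, 1) * 1e-3)
  expect_equal(abs(e$vectors), diag(3), tolerance = 1e-12)

  set.seed(13)
  for (i in 1:50) {
    D <- random_pd_tensor()
    e <- eigensystem(D)
    expect_true(all(diff(e$values) <= 1e-18))
    expect_equal(crossprod(e$vectors), diag(3), tolerance = 1e-6)
    expect_lt(max(abs(e$vectors %*% diag(e$values) %*% t(e$vectors) - D)),
              1e-10)
    # Sign convention: first non-zero component of each vector >= 0.
    for (j in 1:3) {
      nz <- which(abs(e$vectors[, j]) > 1e-12)
      expect_gte(e$vectors[nz[1], j], 0)
    }
  }

  expect_error(eigensystem(c(NA, 0, 0, 0, 0, 0)), "finite")
})

test_that("scalar metrics match their closed forms and identities", {
  iso <- scalar_metrics(c(2e-3, 2e-3, 2e-3))
  expect_equal(iso$fa, 0)
  expect_equal(iso$md, 2e-3)
  expect_equal(iso$ad, 2e-3)
  expect_equal(iso$rd, 2e-3)

  stick <- scalar_metrics(c(1, 0, 0))
  expect_equal(stick$fa, 1, tolerance = 1e-12)
  expect_equal(stick$md, 1 / 3, tolerance = 1e-15)
  expect_equal(stick$ad, 1)
  expect_equal(stick$rd, 0)

  l <- c(1.7e-3, 0.3e-3, 0.2e-3)
  m <- scalar_metrics(l)
  expect_equal(m$md, 7.333333333333333e-4, tolerance = 1e-12)
  expect_equal(m$ad, 1.7e-3)
  expect_equal(m$rd, 2.5e-4)
  lbar <- mean(l)
  expect_equal(m$fa, sqrt(1.5 * sum((l - lbar)^2) / sum(l^2)),
               tolerance = 1e-12)

  # MD = (AD + 2 RD) / 3 holds bitwise; FA stays in [0, 1] for
  # non-negative eigenvalues.
  set.seed(14)
  for (i in 1:100) {
    l <- sort(runif(3, 0, 3e-3), decreasing = TRUE)
    m <- scalar_metrics(l)
    expect_identical(m$md, (m$ad + 2 * m$rd) / 3)
    expect_true(m$fa >= 0 && m$fa <= 1)
  }

  expect_equal(scalar_metrics(c(0, 0, 0))$fa, 0)
})

test_that("metrics are invariant under joint rotation of tensor and gradients", {
  set.seed(15)
  for (i in 1:10) {
    D <- random_pd_tensor()
    R <- random_rotation()
    s <- predict_signal(D, 100, sch42)
    sch_rot <- acquisition_scheme(sch42$bvals, sch42$bvecs %*% t(R))
    # Same physical signals arise from the rotated tensor under rotated
    # gradients; fitting in the rotated frame must give identical metrics.
    s_rot <- predict_signal(R %*% D %*% t(R), 100, sch_rot)
    expect_equal(s_rot, s, tolerance = 1e-10)
    m1 <- scalar_metrics(eigensystem(fit_nlls(s, sch42))$values)
    m2 <- scalar_metrics(eigensystem(fit_nlls(s_rot, sch_rot))$values)
    expect_equal(unlist(m1), unlist(m2), tolerance = 1e-8)
  }
})

test_that("scaling all signals scales s0 and leaves the tensor unchanged", {
  set.seed(16)
  D <- random_pd_tensor()
  s <- predict_signal(D, 100, sch42)
  f1 <- fit_nlls(s, sch42)
  f2 <- fit_nlls(3.7 * s, sch42)
  expect_equal(f2$s0_est, 3.7 * f1$s0_est, tolerance = 1e-8)
  expect_equal(f2$d, f1$d, tolerance = 1e-8)
})

test_that("volume fitting applies the per-voxel chain inside the mask", {
  cfg <- small_phantom(n_control = 2, n_hd = 0, between_subject_cv = 0,
                       within_subject_cv = 0, rician_sigma = 0, seed = 5)
  sch <- default_scheme(12, 2, 1000)
  cohort <- generate_cohort(cfg, sch)
  dwi <- cohort$subjects[[1]]$dwi[[1]]
  truth <- truth_table(cohort)
  fv <- suppressMessages(fit_volume(dwi, sch))

  # Noise-free phantom: FA equals truth everywhere in each region.
  for (r in seq_len(nrow(cfg$region_spec))) {
    sel <- cohort$labels == cfg$region_spec$label_id[r]
    fa_true <- truth$fa[truth$subject_id == "ctrl01" &
                          truth$region == cfg$region_spec$region_name[r]]
    expect_lt(max(abs(fv$fa[sel] - fa_true)), 1e-6)
  }
  expect_true(all(fv$fa[cohort$labels == 0 & !fv$mask] == 0))

  # All-false mask: vacuous output.
  empty <- suppressMessages(
    fit_volume(dwi, sch, mask = array(FALSE, dim(cohort$labels))))
  expect_true(all(empty$fa == 0) && all(empty$md == 0))

  # Per-voxel independence: a map voxel equals the scalar chain applied
  # to that voxel's signal vector alone.
  vox <- which(cohort$labels == 1, arr.ind = TRUE)[1, ]
  sig <- dwi[vox[1], vox[2], vox[3], ]
  m <- scalar_metrics(pmax(eigensystem(fit_nlls(sig, sch))$values, 0))
  expect_equal(fv$fa[vox[1], vox[2], vox[3]], m$fa, tolerance = 1e-12)
  expect_equal(fv$md[vox[1], vox[2], vox[3]], m$md, tolerance = 1e-12)

  expect_error(suppressMessages(fit_volume(dwi, default_scheme(13, 2, 1000))),
               "does not match")
})
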