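test_that("variance components reproduce the one-way ANOVA estimators", {
  # Identical repeats: all variance is between subjects.
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  vc <- variance_components(paired_series(x))
  expect_equal(vc$var_within, 0)
  expect_equal(vc$var_between, stats::var(c(1, 2, 3, 4)))

  # Same differing pair for every subject: between truncated to zero.
  x <- cbind(rep(1, 5), rep(2, 5))
  vc <- variance_components(paired_series(x))
  expect_equal(vc$var_between, 0)
  expect_equal(vc$var_within, 0.5)

  # Random tables against the independent aov oracle.
  set.seed(51)
  for (i in 1:20) {
    x <- matrix(rnorm(16, 10, 2), 8, 2)
    vc <- variance_components(paired_series(x))
    oracle <- aov_vc_oracle(x)
    expect_equal(vc$var_between, oracle$var_between, tolerance = 1e-12)
    expect_equal(vc$var_within, oracle$var_within, tolerance = 1e-12)
  }

  expect_error(paired_series(matrix(1, 1, 2)), "at least 2")
  expect_error(paired_series(cbind(c(1, NA), c(1, 2))), "missing")
})

test_that("ICC is the between-variance fraction, NA when undefined", {
  expect_equal(icc(1, 0), 1)
  expect_equal(icc(0, 1), 0)
  expect_equal(icc(3, 1), 0.75)
  expect_true(is.na(icc(0, 0)))
  expect_error(icc(-1, 1), "non-negative")
})

test_that("delta-method CI matches the closed form, truncates, and scales", {
  # Zero-width interval at rho = 1 on both scales (V = 0 there).
  expect_equal(icc_ci_delta(1, 12), c(ci_low = 1, ci_high = 1))
  expect_equal(icc_ci_delta(1, 12, scale = "linear"),
               c(ci_low = 1, ci_high = 1))

  # Linear Wald form at rho = 0, n = 13: half-width 1.96*sqrt(2/(2*12)),
  # lower bound truncated to 0.
  ci <- icc_ci_delta(0, 13, k = 2, scale = "linear")
  expect_equal(ci[["ci_low"]], 0)
  expect_equal(ci[["ci_high"]],
               min(1, stats::qnorm(0.975) * sqrt(2 / (2 * 12))))

  # Width scales as 1/sqrt(n - 1) at fixed rho (away from truncation):
  # exactly for the linear interval, and on the atanh scale for the
  # variance-stabilized default.
  w <- function(n) unname(diff(icc_ci_delta(0.6, n, scale = "linear")))
  expect_equal(w(21) / w(11), 1 / sqrt(2), tolerance = 1e-9)
  wz <- function(n) unname(diff(atanh(icc_ci_delta(0.6, n))))
  expect_equal(wz(21) / wz(11), 1 / sqrt(2), tolerance = 1e-9)

  # Default interval is a proper subinterval of [0, 1] containing the
  # point estimate.
  ci_z <- icc_ci_delta(0.8, 12)
  expect_lt(ci_z[["ci_low"]], 0.8)
  expect_gt(ci_z[["ci_high"]], 0.8)
  expect_gte(ci_z[["ci_low"]], 0)
  expect_lte(ci_z[["ci_high"]], 1)

  expect_error(icc_ci_delta(0.5, 2), "at least 3")
})

test_that("ICC is invariant to shifting and scaling the measurements", {
  set.seed(52)
  x <- matrix(rnorm(24, 5, 1), 12, 2)
  vc <- variance_components(paired_series(x))
  r0 <- icc(vc$var_between, vc$var_within)
  for (tr in list(function(v) v + 17.3, function(v) v * -2.6,
                  function(v) v * 1e-4 + 3)) {
    vc2 <- variance_components(paired_series(tr(x)))
    expect_equal(icc(vc2$var_between, vc2$var_within), r0,
                 tolerance = 1e-12)
  }
  # Total variance decomposes on balanced data.
  expect_equal(vc$var_between + vc$var_within, (vc$msb + vc$msw) / 2,
               tolerance = 1e-12)
})

test_that("Bland-Altman statistics match hand arithmetic and cover ~95%", {
  x <- cbind(c(1, 2, 3), c(1, 2, 3))
  ba <- bland_altman(paired_series(x))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))

  x <- cbind(c(1, 2, 3), c(1, 2, 3) - 0.1)
  ba <- bland_altman(paired_series(x))
  expect_equal(ba$mean_diff, 0.1)
  expect_equal(ba$sd_diff, 0)

  ba <- bland_altman(paired_series(cbind(c(1, 2, 3), c(2, 2, 5))))
  expect_equal(ba$mean_diff, -1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1 - 1.96)
  expect_equal(ba$loa_high, -1 + 1.96)
  expect_equal(ba$pairs$mean, c(1.5, 2, 4))

  # Limits of agreement contain ~95% of Gaussian differences.
  set.seed(53)
  n <- 1e4
  x <- cbind(rnorm(n, 10, 2), rnorm(n, 10, 2))
  ba <- bland_altman(paired_series(x))
  inside <- mean(ba$pairs$diff >= ba$loa_low & ba$pairs$diff <= ba$loa_high)
  expect_gte(inside, 0.92)
  expect_lte(inside, 0.98)
})

test_that("reliability tables analyse groups separately with summary counts", {
  set.seed(54)
  mk_rows <- function(group, ids, region, metric, v1, v2) {
    data.frame(subject_id = rep(ids, 2), group = group,
               repeat_index = rep(1:2, each = length(ids)),
               region = region, metric = metric, value = c(v1, v2),
               stringsAsFactors = FALSE)
  }
  v1 <- rnorm(6, 0.5, 0.05); v2 <- v1 + rnorm(6, 0, 0.01)
  m <- rbind(
    mk_rows("control", sprintf("c%d", 1:6), "r1", "FA", v1, v2),
    mk_rows("hd", sprintf("h%d", 1:6), "r1", "FA", v1, v2))
  tab <- reliability_table(m)
  expect_equal(nrow(tab), 2)
  # Identical data per group: identical results.
  expect_equal(tab$icc[1], tab$icc[2])
  expect_equal(tab$ci_low[1], tab$ci_low[2])
  expect_equal(tab$var_within[1], tab$var_within[2])

  # Summary counting: 48 regions, 40 above threshold -> 83.33%.
  fake <- data.frame(region = sprintf("r%02d", 1:48), metric = "FA",
                     group = "control", n = 12,
                     icc = c(rep(0.9, 40), rep(0.5, 8)),
                     ci_low = NA, ci_high = NA, var_within = 1,
                     var_between = 1, undefined = FALSE)
  sm <- reliability_summary(fake)
  expect_equal(sm$n_regions, 48)
  expect_equal(sm[["n_icc_ge_0.8"]], 40)
  expect_equal(sm[["pct_icc_ge_0.8"]], 100 * 40 / 48, tolerance = 1e-12)
  expect_equal(sm$mean_icc, mean(fake$icc))

  # Small groups are flagged with the CI omitted.
  small <- mk_rows("control", c("c1", "c2"), "r1", "MD",
                   c(1, 2), c(1.1, 2.1))
  tab2 <- reliability_table(small)
  expect_true(is.na(tab2$ci_low))
  expect_false(is.na(tab2$icc))
})

test_that("simulated cohorts with configured reliability are recovered per region", {
  set.seed(55)
  cv_b <- 0.10
  cv_w <- cv_within_for_icc(0.9, cv_b)
  est <- replicate(12, {
    x <- simulate_retest_series(200, 7e-4, cv_b, cv_w)
    vc <- variance_components(paired_series(x))
    icc(vc$var_between, vc$var_within)
  })
  expect_gte(mean(abs(est - 0.9) <= 0.03), 0.95)
})

test_that("voxelwise ICC equals the scalar path and orders regions correctly", {
  set.seed(56)
  n <- 8
  grid <- c(5L, 5L, 5L)
  stack1 <- array(rnorm(prod(grid) * n, 1, 0.3), dim = c(grid, n))
  stack2 <- array(rnorm(prod(grid) * n, 1, 0.3), dim = c(grid, n))

  res <- suppressMessages(voxelwise_icc(stack1, stack2))
  # Plain-loop oracle over every voxel, scalar pipeline per voxel.
  for (v in seq_len(prod(grid))) {
    idx <- arrayInd(v, grid)
    ser <- paired_series(cbind(stack1[idx[1], idx[2], idx[3], ],
                               stack2[idx[1], idx[2], idx[3], ]))
    vc <- variance_components(ser)
    expect_identical(res$icc[v], icc(vc$var_between, vc$var_within))
  }

  # Identical streams with between-subject variance: ICC = 1 everywhere.
  res1 <- suppressMessages(voxelwise_icc(stack1, stack1))
  expect_true(all(res1$icc == 1))

  # True voxel ICC 0.8 in region A vs 0.4 in region B: map means ordered.
  nA <- 60
  mkstack <- function(target_icc, nvox) {
    cvw <- cv_within_for_icc(target_icc, 0.10)
    arr1 <- arr2 <- matrix(0, nvox, nA)
    for (v in seq_len(nvox)) {
      x <- simulate_retest_series(nA, 1, 0.10, cvw)
      arr1[v, ] <- x[, 1]; arr2[v, ] <- x[, 2]
    }
    list(arr1, arr2)
  }
  sA <- mkstack(0.8, 20); sB <- mkstack(0.4, 20)
  s1 <- array(rbind(sA[[1]], sB[[1]]), dim = c(40, 1, 1, nA))
  s2 <- array(rbind(sA[[2]], sB[[2]]), dim = c(40, 1, 1, nA))
  m <- suppressMessages(voxelwise_icc(s1, s2))$icc
  expect_gt(mean(m[1:20, , ]), mean(m[21:40, , ]))

  expect_error(suppressMessages(
    voxelwise_icc(stack1, stack2, subject_ids1 = letters[1:8],
                  subject_ids2 = letters[8:1])), "subject order")
})

test_that("leave-one-out sensitivity recomputes and inverts cleanly", {
  set.seed(57)
  base <- matrix(rnorm(20, 1, 0.2), 10, 2)
  base[, 2] <- base[, 1] + rnorm(10, 0, 0.02)
  ids <- sprintf("s%02d", 1:10)

  # A subject at the group mean: dropping changes the result only via n.
  mean_pair <- colMeans(base)
  x <- rbind(base, mean_pair)
  ser <- paired_series(x, c(ids, "mean_subj"))
  out <- outlier_sensitivity(ser, "mean_subj")
  recompute <- reliability_result(paired_series(base, ids))
  expect_equal(out$after$icc, recompute$icc)
  expect_equal(out$after$n, 10)

  # One extreme-discordant subject: removal increases the ICC.
  disc <- rbind(base, c(1.0, 2.5))
  ser2 <- paired_series(disc, c(ids, "outlier"))
  out2 <- outlier_sensitivity(ser2, "outlier")
  expect_gt(out2$after$icc, out2$before$icc)

  # Drop then re-add is the identity.
  kept <- paired_series(ser2$values[ser2$subject_ids != "outlier", ],
                        ids)
  readded <- paired_series(rbind(kept$values, c(1.0, 2.5)),
                           c(ids, "outlier"))
  expect_equal(reliability_result(readded)$icc,
               reliability_result(ser2)$icc)

  expect_error(outlier_sensitivity(paired_series(base[1:3, ]), "s01"),
               "at least 4")
  expect_error(outlier_sensitivity(ser2, "nope"), "not in the series")
})
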