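# Synthetic repeated-measures DWI cohorts with known ground truth.
#
# The phantom is a small voxel grid holding axis-aligned box and sphere
# regions, each with its own mean tensor. Subject- and scan-level
# variability enter as multiplicative log-normal scalings of the region
# eigenvalues (unit mean, configurable coefficient of variation), which
# preserves positive-definiteness by construction. Magnitude noise is
# Rician. Every subject and scan has its own random sub-stream derived from
# the global seed and the subject id, so adding subjects never changes the
# data of existing ones.

#' Default phantom region specification
#'
#' Six regions in a 20 x 20 x 10 grid emulating the region types analysed
#' in test-retest DTI studies of Huntington's disease: bilateral caudate
#' and putamen (grey matter, near-isotropic tensors), a cerebral white
#' matter slab, and a corpus callosum block (both strongly anisotropic).
#' The `fa_thresholded` flag marks white-matter atlas-style regions whose
#' means are computed under a template FA > 0.2 mask; grey-matter
#' (T1-segmentation style) regions are never thresholded.
#'
#' Geometry is given in 0-based voxel indices: spheres by `cx, cy, cz,
#' radius`, boxes by inclusive bounds `x0..x1, y0..y1, z0..z1`.
#'
#' @return A data.frame with columns `label_id`, `region_name`, `shape`,
#'   geometry columns, eigenvalues `l1 >= l2 >= l3` (mm^2/s), principal
#'   direction `dx, dy, dz`, and `fa_thresholded`.
#' @export
default_region_spec <- function() {
  data.frame(
    label_id = 1:6,
    region_name = c("caudate_left", "caudate_right", "putamen_left",
                    "putamen_right", "cerebral_white_matter",
                    "corpus_callosum"),
    shape = c("sphere", "sphere", "sphere", "sphere", "box", "box"),
    cx = c(6, 13, 6, 13, NA, NA),
    cy = c(6, 6, 13, 13, NA, NA),
    cz = c(2, 2, 2, 2, NA, NA),
    radius = c(2, 2, 2, 2, NA, NA),
    x0 = c(NA, NA, NA, NA, 3, 4), x1 = c(NA, NA, NA, NA, 16, 15),
    y0 = c(NA, NA, NA, NA, 3, 8), y1 = c(NA, NA, NA, NA, 16, 11),
    z0 = c(NA, NA, NA, NA, 5, 8), z1 = c(NA, NA, NA, NA, 6, 9),
    l1 = c(0.85e-3, 0.85e-3, 0.85e-3, 0.85e-3, 1.40e-3, 1.70e-3),
    l2 = c(0.65e-3, 0.65e-3, 0.65e-3, 0.65e-3, 0.45e-3, 0.30e-3),
    l3 = c(0.60e-3, 0.60e-3, 0.60e-3, 0.60e-3, 0.40e-3, 0.25e-3),
    dx = c(1, 1, 1, 1, 0, 1),
    dy = c(0, 0, 0, 0, 1, 0),
    dz = c(0, 0, 0, 0, 0, 0),
    fa_thresholded = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Phantom cohort configuration
#'
#' Bundles everything that defines a simulated test-retest cohort: the
#' voxel grid, the region specification (see [default_region_spec()]),
#' group sizes, the two variance sources, the Rician noise scale, and the
#' global seed.
#'
#' Variability model: each subject draws one log-normal eigenvalue scaling
#' per region (unit mean, CV `between_subject_cv`, multiplied by
#' `hd_between_scale` for the disease group); each scan additionally draws
#' one log-normal scan-level scaling (CV `within_subject_cv`) applied to
#' all regions, representing scanner/physiological scan-to-scan drift.
#' Because a common scaling of all three eigenvalues leaves FA unchanged,
#' anisotropy variability is generated separately by trace-preserving
#' "shape" factors: eigenvalues are stretched about their mean,
#' \eqn{\lambda \to \bar\lambda + (\lambda - \bar\lambda) F}, with
#' unit-mean log-normal `F` per subject (CV `anisotropy_between_cv`) and
#' per scan (CV `anisotropy_within_cv`). Shape factors change FA but leave
#' MD exactly unchanged, so the diffusivity variance structure implied by
#' the two main CVs is preserved to the last bit. By default the
#' anisotropy CVs track the main CVs at half their size, so zeroing the
#' main CVs silences all variability.
#' The disease group's mean eigenvalues are shifted by `hd_md_shift`
#' (relative diffusivity increase in all regions) and, in FA-thresholded
#' white-matter regions, flattened towards isotropy by `hd_fa_shift`.
#'
#' @param grid_shape Integer vector of 3 positive extents (voxels).
#' @param region_spec Region data.frame, see [default_region_spec()].
#' @param n_control,n_hd Group sizes (non-negative integers).
#' @param between_subject_cv Coefficient of variation of the per-subject
#'   eigenvalue scaling (between-subject variability).
#' @param within_subject_cv Coefficient of variation of the per-scan
#'   scaling (within-subject, scan-rescan variability).
#' @param rician_sigma Rician noise scale in signal units.
#' @param s0 Non-diffusion-weighted signal amplitude inside regions.
#' @param seed Integer global seed.
#' @param hd_md_shift Relative diffusivity increase in the disease group.
#' @param hd_fa_shift Relative eigenvalue flattening towards isotropy in
#'   FA-thresholded regions for the disease group.
#' @param hd_between_scale Multiplier on `between_subject_cv` for the
#'   disease group (disease cohorts are typically more heterogeneous).
#' @param anisotropy_between_cv,anisotropy_within_cv CVs of the
#'   trace-preserving eigenvalue shape factors at the subject and scan
#'   level; `NULL` (default) uses half the corresponding main CV.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(20L, 20L, 10L),
                           region_spec = default_region_spec(),
                           n_control = 12L, n_hd = 10L,
                           between_subject_cv = 0.10,
                           within_subject_cv = 0.02,
                           rician_sigma = 2, s0 = 100, seed = 42L,
                           hd_md_shift = 0.10, hd_fa_shift = 0.10,
                           hd_between_scale = 1.5,
                           anisotropy_between_cv = NULL,
                           anisotropy_within_cv = NULL) {
  if (is.null(anisotropy_between_cv))
    anisotropy_between_cv <- between_subject_cv / 2
  if (is.null(anisotropy_within_cv))
    anisotropy_within_cv <- within_subject_cv / 2
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_config("grid_shape must be 3 positive integers")
  if (!is.data.frame(region_spec) || nrow(region_spec) == 0L)
    stop_config("region_spec must be a non-empty data.frame")
  if (anyDuplicated(region_spec$label_id) || any(region_spec$label_id <= 0))
    stop_config("region label_ids must be unique positive integers ",
                "(0 is reserved for background)")
  lam <- as.matrix(region_spec[, c("l1", "l2", "l3")])
  if (any(lam < 0) || any(lam[, 1] < lam[, 2]) || any(lam[, 2] < lam[, 3]))
    stop_config("region eigenvalues must be non-negative and sorted ",
                "l1 >= l2 >= l3")
  for (v in c(between_subject_cv, within_subject_cv, rician_sigma,
              anisotropy_between_cv, anisotropy_within_cv))
    if (!is.finite(v) || v < 0)
      stop_config("CVs and rician_sigma must be non-negative")
  if (s0 <= 0) stop_config("s0 must be positive")
  if (n_control < 0 || n_hd < 0) stop_config("group sizes must be >= 0")
  structure(list(grid_shape = grid_shape, region_spec = region_spec,
                 n_control = as.integer(n_control), n_hd = as.integer(n_hd),
                 between_subject_cv = between_subject_cv,
                 within_subject_cv = within_subject_cv,
                 rician_sigma = rician_sigma, s0 = s0,
                 seed = as.integer(seed),
                 hd_md_shift = hd_md_shift, hd_fa_shift = hd_fa_shift,
                 hd_between_scale = hd_between_scale,
                 anisotropy_between_cv = anisotropy_between_cv,
                 anisotropy_within_cv = anisotropy_within_cv),
            class = "phantom_config")
}

# Integer label volume from a region specification; errors if a region has
# no voxels inside the grid or if regions overlap.
build_labels <- function(config) {
  g <- config$grid_shape
  labels <- array(0L, dim = g)
  co <- expand.grid(x = 0:(g[1] - 1), y = 0:(g[2] - 1), z = 0:(g[3] - 1))
  for (i in seq_len(nrow(config$region_spec))) {
    r <- config$region_spec[i, ]
    sel <- if (r$shape == "sphere") {
      (co$x - r$cx)^2 + (co$y - r$cy)^2 + (co$z - r$cz)^2 <= r$radius^2
    } else if (r$shape == "box") {
      co$x >= r$x0 & co$x <= r$x1 & co$y >= r$y0 & co$y <= r$y1 &
        co$z >= r$z0 & co$z <= r$z1
    } else stop_config("unknown region shape: ", r$shape)
    if (!any(sel))
      stop_config("grid too small: region '", r$region_name,
                  "' contains no voxels")
    if (any(labels[sel] != 0L))
      stop_config("region '", r$region_name, "' overlaps another region")
    labels[sel] <- as.integer(r$label_id)
  }
  labels
}

# Symmetric tensor with eigenvalues lam (descending) and principal axis dir.
tensor_from_direction <- function(lam, dir) {
  e1 <- dir / sqrt(sum(dir^2))
  helper <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- c(e1[2] * helper[3] - e1[3] * helper[2],
          e1[3] * helper[1] - e1[1] * helper[3],
          e1[1] * helper[2] - e1[2] * helper[1])
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  lam[1] * tcrossprod(e1) + lam[2] * tcrossprod(e2) + lam[3] * tcrossprod(e3)
}

# Trace-preserving eigenvalue shape change: stretch the eigenvalues about
# their mean by factor f. MD is exactly invariant; f is capped at the
# largest value keeping the smallest eigenvalue non-negative.
shape_lambda <- function(lam, f) {
  lbar <- mean(lam)
  if (lam[3] < lbar) f <- min(f, lbar / (lbar - lam[3]))
  lbar + (lam - lbar) * f
}

# Group-adjusted mean eigenvalues for one region.
region_lambda <- function(config, region_row, group) {
  lam <- as.numeric(region_row[c("l1", "l2", "l3")])
  if (group == "hd") {
    lam <- lam * (1 + config$hd_md_shift)
    if (isTRUE(region_row$fa_thresholded)) {
      lbar <- mean(lam)
      lam <- lbar + (lam - lbar) * (1 - config$hd_fa_shift)
    }
  }
  lam
}

#' Generate a ground-truth test-retest cohort
#'
#' Simulates the full repeated-measures design: for every subject a
#' per-region eigenvalue scaling is drawn once (between-subject
#' variability, with group-specific mean tensors for the disease group),
#' then each of the two back-to-back scans draws an independent scan-level
#' scaling (within-subject variability) and independent Rician noise.
#' Fully reproducible from `config$seed`; the true per-subject tensor
#' field is stored alongside the noisy data. Uses [set.seed()] internally.
#'
#' @param config A [phantom_config()].
#' @param scheme An [acquisition_scheme()]; defaults to the 42-direction
#'   b = 1000 s/mm^2 + 7 b = 0 protocol of [default_scheme()].
#' @return An object of class `dwi_cohort`: list with `subjects` (each a
#'   list of `subject_id`, `group`, `truth_lambda` region x 3 matrix of
#'   true subject eigenvalues, `tensor_truth` 4D 6-component array, `dwi`
#'   list of two 4D repeat volumes), plus `labels`, `scheme`, `config`.
#' @export
generate_cohort <- function(config, scheme = default_scheme()) {
  if (!inherits(config, "phantom_config"))
    stop_config("config must be a phantom_config")
  labels <- build_labels(config)
  grid <- config$grid_shape
  nvox <- prod(grid)
  nvol <- length(scheme$bvals)
  spec <- config$region_spec
  region_voxels <- lapply(spec$label_id, function(id) which(labels == id))

  make_subject <- function(subject_id, group) {
    cvb <- config$between_subject_cv *
      if (group == "hd") config$hd_between_scale else 1
    set.seed(derive_seed(config$seed, "subject", subject_id))
    A <- rlnorm_cv(nrow(spec), cvb)
    Fsubj <- rlnorm_cv(nrow(spec), config$anisotropy_between_cv)
    truth_lambda <- matrix(0, nrow(spec), 3,
                           dimnames = list(spec$region_name, NULL))
    dirs <- vector("list", nrow(spec))
    tensor_truth <- array(0, dim = c(grid, 6L))
    tt <- matrix(0, nvox, 6L)
    for (i in seq_len(nrow(spec))) {
      lam <- shape_lambda(region_lambda(config, spec[i, ], group) * A[i],
                          Fsubj[i])
      truth_lambda[i, ] <- lam
      dirs[[i]] <- as.numeric(spec[i, c("dx", "dy", "dz")])
      D <- tensor_from_direction(lam, dirs[[i]])
      tt[region_voxels[[i]], ] <- matrix(
        c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3]),
        length(region_voxels[[i]]), 6L, byrow = TRUE)
    }
    tensor_truth[] <- tt
    dwi <- vector("list", 2L)
    for (rep_i in 1:2) {
      set.seed(derive_seed(config$seed, "scan", subject_id, rep_i))
      E <- rlnorm_cv(1L, config$within_subject_cv)
      Fscan <- rlnorm_cv(1L, config$anisotropy_within_cv)
      sig <- matrix(0, nvox, nvol)
      for (i in seq_len(nrow(spec))) {
        lam_scan <- shape_lambda(truth_lambda[i, ], Fscan) * E
        D_scan <- tensor_from_direction(lam_scan, dirs[[i]])
        sig[region_voxels[[i]], ] <- matrix(
          predict_signal(D_scan, config$s0, scheme),
          length(region_voxels[[i]]), nvol, byrow = TRUE)
      }
      if (config$rician_sigma > 0) {
        set.seed(derive_seed(config$seed, "noise", subject_id, rep_i))
        sig <- matrix(add_rician_noise(as.vector(sig), config$rician_sigma),
                      nvox, nvol)
      }
      dwi[[rep_i]] <- array(sig, dim = c(grid, nvol))
    }
    list(subject_id = subject_id, group = group,
         truth_lambda = truth_lambda, tensor_truth = tensor_truth,
         dwi = dwi)
  }

  ids <- c(sprintf("ctrl%02d", seq_len(config$n_control)),
           sprintf("hd%02d", seq_len(config$n_hd)))
  groups <- c(rep("control", config$n_control), rep("hd", config$n_hd))
  subjects <- Map(make_subject, ids, groups)
  structure(list(subjects = subjects, labels = labels, scheme = scheme,
                 config = config), class = "dwi_cohort")
}

#' @export
print.dwi_cohort <- function(x, ...) {
  cat(sprintf(
    "DWI test-retest cohort: %d subjects (%d control, %d hd), grid %s, %d regions, %d volumes/scan\n",
    length(x$subjects), x$config$n_control, x$config$n_hd,
    paste(x$config$grid_shape, collapse = "x"),
    nrow(x$config$region_spec), length(x$scheme$bvals)))
  invisible(x)
}

#' Ground-truth region metrics of a cohort
#'
#' Tabulates, for every subject and region, the scalar metrics implied by
#' the subject's true (noise-free, scan-average) eigenvalues.
#'
#' @param cohort A `dwi_cohort` from [generate_cohort()].
#' @return data.frame with columns `subject_id`, `group`, `region`, `fa`,
#'   `md`, `ad`, `rd`.
#' @export
truth_table <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    m <- t(apply(s$truth_lambda, 1L, function(l)
      unlist(scalar_metrics(l))))
    data.frame(subject_id = s$subject_id, group = s$group,
               region = rownames(s$truth_lambda),
               fa = m[, "fa"], md = m[, "md"], ad = m[, "ad"], rd = m[, "rd"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate paired region-mean measurements directly
#'
#' Fast path through the cohort generative model for a single region-mean
#' quantity: measurement `x[i, j] = mu * A[i] * E[i, j]` with unit-mean
#' log-normal subject factors `A` (CV `cv_between`) and scan factors `E`
#' (CV `cv_within`). This is the same scaling kernel used voxelwise by
#' [generate_cohort()], without image synthesis or tensor fitting, and is
#' the tool of choice for reliability calibration experiments at large `n`.
#'
#' @param n Number of subjects.
#' @param mu True mean of the measurement (e.g. region-mean MD in mm^2/s).
#' @param cv_between,cv_within Coefficients of variation of the subject and
#'   scan scaling factors.
#' @param seed Optional integer seed (uses [set.seed()] when given).
#' @return An `n` x 2 matrix of paired measurements.
#' @seealso [implied_retest_icc()] for the population ICC these settings
#'   imply.
#' @export
simulate_retest_series <- function(n, mu = 7e-4, cv_between = 0.10,
                                   cv_within = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- rlnorm_cv(n, cv_between)
  E <- matrix(rlnorm_cv(2L * n, cv_within), n, 2L)
  mu * A * E
}

#' Population reliability implied by the scaling model
#'
#' For measurements `x = mu * A * E` with independent unit-mean log-normal
#' factors, the between-subject variance is `mu^2 * cv_b^2` and the
#' within-subject variance is `mu^2 * (1 + cv_b^2) * cv_w^2`, so the
#' population intraclass correlation is
#' `cv_b^2 / (cv_b^2 + (1 + cv_b^2) * cv_w^2)`.
#'
#' @param cv_between,cv_within Coefficients of variation of the subject and
#'   scan factors.
#' @param mu True mean (only used by `implied_retest_variances()`).
#' @return `implied_retest_icc()`: the population ICC.
#'   `implied_retest_variances()`: list with `var_between`, `var_within`.
#'   `cv_within_for_icc()`: the `cv_within` that yields a target ICC at a
#'   given `cv_between`.
#' @export
implied_retest_icc <- function(cv_between, cv_within) {
  cv_between^2 / (cv_between^2 + (1 + cv_between^2) * cv_within^2)
}

#' @rdname implied_retest_icc
#' @export
implied_retest_variances <- function(mu, cv_between, cv_within) {
  list(var_between = mu^2 * cv_between^2,
       var_within = mu^2 * (1 + cv_between^2) * cv_within^2)
}

#' @rdname implied_retest_icc
#' @param icc Target population ICC in (0, 1].
#' @export
cv_within_for_icc <- function(icc, cv_between = 0.10) {
  if (icc <= 0 || icc > 1) stop_data("icc must be in (0, 1]")
  sqrt(cv_between^2 * (1 - icc) / (icc * (1 + cv_between^2)))
}
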